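#' A genomic region class for diversity analyses
#'
#' Bundles a label (e.g. `"mature"`, `"loop"`, `"CDS"`) with a set of
#' non-overlapping intervals.
#'
#' @param label Region class label.
#' @param intervals Data frame with `chrom`, `start`, `end` columns.
#' @return List of class `region_class`.
#' @export
region_class <- function(label, intervals) {
  total <- sum(intervals$end - intervals$start)
  if (total <= 0) stop("region class has zero total length")
  merged <- merge_intervals(intervals[, c("chrom", "start", "end")])
  if (sum(merged$end - merged$start) != total) {
    stop(sprintf("intervals of region class '%s' overlap", label))
  }
  structure(list(label = label, intervals = intervals, total_length = total),
            class = "region_class")
}

#' Region classes of miRNA sub-regions
#'
#' Builds the five miRNA-derived region classes (mature, star, loop and
#' the two 30-nt flanks) from a miRNA table.
#'
#' @param mirnas Reference miRNA table.
#' @return Named list of [region_class()] objects.
#' @export
mirna_region_classes <- function(mirnas) {
  take <- function(prefix) {
    s <- mirnas[[paste0(prefix, "_start")]]
    e <- mirnas[[paste0(prefix, "_end")]]
    ok <- !is.na(s) & !is.na(e)
    data.frame(chrom = mirnas$chrom[ok], start = s[ok], end = e[ok],
               stringsAsFactors = FALSE)
  }
  labels <- c(mature = "mature", star = "star", loop = "loop",
              flank5 = "5p-flank", flank3 = "3p-flank")
  out <- list()
  for (nm in names(labels)) {
    iv <- take(nm)
    if (nrow(iv) > 0) out[[labels[[nm]]]] <- region_class(labels[[nm]], iv)
  }
  out
}

#' Variants falling inside a region class
#'
#' Subset of the variant table whose positions `p` satisfy
#' `start <= p < end` for some interval of the class.
#'
#' @param rc A [region_class()].
#' @param variants Variant data frame with `chrom`, `pos` columns.
#' @return The matching rows of `variants`.
#' @export
variants_in_class <- function(rc, variants) {
  inside <- rep(FALSE, nrow(variants))
  for (r in seq_len(nrow(rc$intervals))) {
    iv <- rc$intervals[r, ]
    inside <- inside | (variants$chrom == iv$chrom &
                          variants$pos >= iv$start & variants$pos < iv$end)
  }
  variants[inside, , drop = FALSE]
}

#' SNP density of a region class
#'
#' Number of variants falling into the class's intervals, normalized by
#' the total class length and scaled to 1 kb.
#'
#' @param rc A [region_class()].
#' @param variants Variant data frame (see [read_variants_vcf()]).
#' @return SNPs per kb.
#' @export
snp_density <- function(rc, variants) {
  1000 * nrow(variants_in_class(rc, variants)) / rc$total_length
}

#' Per-interval SNP densities of a region class
#'
#' One density value per interval (e.g. per miRNA gene), the unit of
#' observation for the two-sample comparison.
#'
#' @inheritParams snp_density
#' @return Numeric vector, one SNPs-per-kb value per interval.
#' @export
snp_density_per_interval <- function(rc, variants) {
  vapply(seq_len(nrow(rc$intervals)), function(r) {
    iv <- rc$intervals[r, ]
    n <- sum(variants$chrom == iv$chrom & variants$pos >= iv$start &
               variants$pos < iv$end)
    1000 * n / (iv$end - iv$start)
  }, numeric(1))
}

#' Minor-allele-frequency bin fractions
#'
#' Fractions of variants with rare (MAF < 0.0001), uncommon
#' (0.0001 <= MAF < 0.01) and common (MAF >= 0.01) minor allele
#' frequencies.
#'
#' @param maf Numeric vector of minor allele frequencies in \[0, 0.5\].
#' @return Named numeric vector `c(rare, uncommon, common)` summing to 1,
#'   or all-`NA` for an empty input (undefined).
#' @export
maf_fractions <- function(maf) {
  if (length(maf) == 0) {
    return(stats::setNames(rep(NA_real_, 3), c("rare", "uncommon", "common")))
  }
  stopifnot(all(maf >= 0 & maf <= 0.5))
  n <- length(maf)
  stats::setNames(c(sum(maf < 1e-4), sum(maf >= 1e-4 & maf < 0.01),
                    sum(maf >= 0.01)) / n,
                  c("rare", "uncommon", "common"))
}

#' Compare per-interval SNP densities of two region classes
#'
#' Welch two-sample t-test on the per-interval density vectors.
#'
#' @param a,b Numeric vectors of per-interval densities (length >= 2
#'   each).
#' @return `htest` object (see [stats::t.test()]).
#' @export
compare_densities <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two observations per class")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # zero-variance limit: Welch statistic degenerates
    same <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = c(t = if (same) 0 else sign(mean(a) - mean(b)) * Inf),
                p.value = if (same) 1 else 0,
                estimate = c(`mean of x` = mean(a), `mean of y` = mean(b)),
                method = "Welch Two Sample t-test (degenerate variance)",
                alternative = "two.sided",
                data.name = "a and b")
    class(res) <- "htest"
    return(res)
  }
  stats::t.test(a, b, var.equal = FALSE)
}
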