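#' Genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open (BED
#' convention): `start` is the first base included, `end` the first base
#' excluded, so `end - start` is the interval length. Conversion from the
#' 1-based, inclusive GFF3 convention happens only in [read_gene_annotation()].
#'
#' @param chrom Chromosome / sequence identifier (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' gi("chr1", 0, 100)
#' @export
gi <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), nchar(chrom) > 0)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(start >= end)) {
    stop("invalid interval: need 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Overlap length of two genomic intervals
#'
#' Returns the number of shared positions. Intervals on different
#' chromosomes do not overlap; strand is ignored, since positional
#' agreement (not orientation) is the criterion used to accept a predicted
#' locus as matching an annotated one.
#'
#' @param a,b One-row interval data frames (see [gi()]).
#' @return Integer overlap length in nucleotides (0 if disjoint).
#' @export
interval_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of DNA strings (`A`, `C`, `G`, `T`, `N` and
#'   IUPAC ambiguity codes).
#' @return Reverse complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                 "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Construct a genome-sequence object
#'
#' @param seqs Named character vector of chromosome sequences (uppercase
#'   DNA). Names must be unique.
#' @param assembly Optional assembly label.
#' @return An object of class `genome_sequence`.
#' @export
genome_sequence <- function(seqs, assembly = "unknown") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("chromosome names must be present and unique")
  }
  seqs <- toupper(seqs)
  obj <- list(seqs = seqs, assembly = assembly,
              lengths = stats::setNames(nchar(seqs), names(seqs)),
              enc = lapply(seqs, encode_dna))
  class(obj) <- "genome_sequence"
  obj
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> assembly '%s': %d sequence(s), %s nt total\n",
              x$assembly, length(x$seqs),
              format(sum(as.numeric(x$lengths)), big.mark = ",")))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) length(x$seqs)

#' Extract a genomic interval's sequence
#'
#' Plus-strand intervals return the forward substring; minus-strand
#' intervals return its reverse complement (the transcribed orientation).
#'
#' @param genome A [genome_sequence()] object.
#' @param iv A one-row interval data frame (see [gi()]).
#' @return The nucleotide string of length `end - start`.
#' @export
extract_sequence <- function(genome, iv) {
  if (!iv$chrom %in% names(genome$seqs)) {
    stop(sprintf("chromosome '%s' not in genome", iv$chrom))
  }
  len <- genome$lengths[[iv$chrom]]
  if (iv$start < 0L || iv$end > len) {
    stop(sprintf("interval %s:%d-%d out of bounds (length %d)",
                 iv$chrom, iv$start, iv$end, len))
  }
  s <- substr(genome$seqs[[iv$chrom]], iv$start + 1L, iv$end)
  if (iv$strand == "-") s <- reverse_complement(s)
  s
}

# integer-encode a DNA string for the C++ kernels (A=0 C=1 G=2 T=3, else -1)
encode_dna <- function(x) {
  code <- chartr("ACGT", "0123", toupper(x))
  v <- utf8ToInt(code) - utf8ToInt("0")
  v[v < 0L | v > 3L] <- -1L
  as.integer(v)
}

# merge overlapping/adjacent intervals on one chromosome (strand-agnostic)
merge_intervals <- function(df) {
  if (nrow(df) <= 1L) return(df)
  out <- list()
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    for (r in seq_len(nrow(d))[-1]) {
      if (d$start[r] <= cur$end) {
        cur$end <- max(cur$end, d$end[r])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- d[r, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
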