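#' Parameters of the targeted ortholog search
#'
#' @param mode `"quick"` (similarity hits of the reference pre-miRNA,
#'   extended, define candidate regions) or `"exhaustive"` (tiling windows
#'   over every chromosome).
#' @param extension Extension (nt) added up- and downstream of each quick
#'   hit; exhaustive windows have length `2 * extension`.
#' @param threshold Minimum accepted score as a fraction of the model's
#'   reference score (default 0.5).
#' @param stride Window stride for exhaustive mode; `NULL` (default) tiles
#'   with an overlap of twice the model length so no locus is split.
#' @return List of class `search_params`.
#' @export
search_params <- function(mode = c("quick", "exhaustive"),
                          extension = 1000L, threshold = 0.5,
                          stride = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1, extension >= 0)
  structure(list(mode = mode, extension = as.integer(extension),
                 threshold = threshold, stride = stride),
            class = "search_params")
}

#' Candidate regions for the targeted search
#'
#' @param mirna One-row miRNA table entry (quick mode queries with its
#'   pre-miRNA sequence).
#' @param genome Target [genome_sequence()].
#' @param params [search_params()].
#' @param blast [blast_params()] for the quick-mode pre-filter.
#' @param model_length Model length, used for the exhaustive tiling
#'   overlap.
#' @return Data frame of intervals (merged, clipped to chromosome bounds).
#' @export
candidate_regions <- function(mirna, genome, params = search_params(),
                              blast = blast_params(), model_length = NULL) {
  if (params$mode == "quick") {
    hits <- local_search(mirna$sequence, genome, blast)
    if (nrow(hits) == 0) return(hits[, c("chrom", "start", "end")])
    regions <- data.frame(
      chrom = hits$chrom,
      start = pmax(0L, hits$start - params$extension),
      end = pmin(unname(genome$lengths[hits$chrom]),
                 hits$end + params$extension),
      stringsAsFactors = FALSE)
    return(merge_intervals(regions))
  }
  # exhaustive: tile every chromosome
  width <- 2L * params$extension
  if (is.null(model_length)) model_length <- 100L
  stride <- if (is.null(params$stride)) {
    max(1L, width - 2L * as.integer(model_length))
  } else {
    as.integer(params$stride)
  }
  out <- list()
  for (chrom in names(genome$seqs)) {
    len <- genome$lengths[[chrom]]
    starts <- unique(c(seq(0L, max(0L, len - 1L), by = stride)))
    starts <- starts[starts < len]
    ends <- pmin(len, starts + width)
    keep <- ends > starts
    out[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# best model hit within an encoded sequence segment; free sequence ends,
# i.e. the maximum over all substrings of a global alignment to the model
scan_segment <- function(model, enc, offset = 0L) {
  al <- profile_align_cpp(enc, model$emis, model$gap, TRUE)
  list(score = al$score + pair_bonus(model, enc, al$cols),
       start = offset + al$start, end = offset + al$end)
}

# all non-overlapping model hits scoring >= min_keep within a sequence,
# found by recursive best-hit extraction
scan_hits_recursive <- function(model, enc, min_keep, offset = 0L) {
  min_len <- max(4L, as.integer(floor(0.5 * model$L)))
  if (length(enc) < min_len) return(NULL)
  hit <- scan_segment(model, enc, offset)
  if (hit$score < min_keep || hit$end <= hit$start) return(NULL)
  left <- right <- NULL
  li <- hit$start - offset          # local coordinates of the hit
  ri <- hit$end - offset
  if (li >= min_len) {
    left <- scan_hits_recursive(model, enc[seq_len(li)], min_keep, offset)
  }
  if (length(enc) - ri >= min_len) {
    right <- scan_hits_recursive(model, enc[(ri + 1L):length(enc)],
                                 min_keep, offset + ri)
  }
  rbind(left, data.frame(start = hit$start, end = hit$end,
                         score = hit$score), right)
}

# accelerated variant for long sequences: an ungapped diagonal sweep
# prefilters candidate offsets before the exact gapped scan is applied to
# the surviving windows (profile-search filter-pipeline style). The filter
# is a heuristic: a hit whose alignment lies on one diagonal (no indels)
# survives whenever its emission sum reaches min_keep - slack; hits that
# only reach the threshold through indels or large positive covariation
# bonuses can in principle be lost, as with the ungapped acceleration
# filters of standard profile-search pipelines.
scan_hits_filtered <- function(model, enc, min_keep, slack = 15) {
  L <- model$L
  if (length(enc) < L + 50L || length(enc) < 4L * L) {
    return(scan_hits_recursive(model, enc, min_keep))
  }
  filt <- min_keep - slack
  ds <- diag_scores_cpp(enc, model$emis)
  cand <- which(ds >= filt)
  if (length(cand) == 0) return(NULL)
  grp <- cumsum(c(1L, diff(cand) > L))
  hits <- NULL
  for (g in unique(grp)) {
    d <- cand[grp == g]
    w0 <- max(1L, min(d) - L)
    w1 <- min(length(enc), max(d) + 2L * L)
    hits <- rbind(hits, scan_hits_recursive(model, enc[w0:w1], min_keep,
                                            offset = w0 - 1L))
  }
  hits
}

#' Scan a genomic region with a profile model
#'
#' Both strands of the region are scanned and the best-scoring sub-hit is
#' returned (ties: smaller start, then plus strand). The scan maximizes
#' over all sub-windows of the region via a free-end-gap alignment, so a
#' verbatim copy of the reference recovers exactly the reference score.
#'
#' @param model A `mirna_cm` model.
#' @param genome [genome_sequence()].
#' @param region One-row interval data frame.
#' @return List with `chrom`, `start`, `end` (absolute), `strand`,
#'   `score`.
#' @export
scan_region <- function(model, genome, region) {
  seq_fwd <- extract_sequence(genome, gi(region$chrom, region$start,
                                         region$end, "+"))
  n <- nchar(seq_fwd)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
    hit <- scan_segment(model, encode_dna(s), 0L)
    if (strand == "-") {
      tmp <- hit
      hit$start <- n - tmp$end
      hit$end <- n - tmp$start
    }
    abs_start <- region$start + hit$start
    abs_end <- region$start + hit$end
    cand <- list(chrom = region$chrom, start = abs_start, end = abs_end,
                 strand = strand, score = hit$score)
    better <- is.null(best) || cand$score > best$score ||
      (cand$score == best$score &&
         (cand$start < best$start ||
            (cand$start == best$start && cand$strand == "+" &&
               best$strand == "-")))
    if (better) best <- cand
  }
  best
}

# all above-threshold hits within a region, both strands, absolute coords
scan_region_hits <- function(model, genome, region, min_keep) {
  seq_fwd <- extract_sequence(genome, gi(region$chrom, region$start,
                                         region$end, "+"))
  n <- nchar(seq_fwd)
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
    hits <- scan_hits_filtered(model, encode_dna(s), min_keep)
    if (is.null(hits) || nrow(hits) == 0) next
    if (strand == "-") {
      tmp <- hits
      hits$start <- n - tmp$end
      hits$end <- n - tmp$start
    }
    hits$chrom <- region$chrom
    hits$start <- region$start + hits$start
    hits$end <- region$start + hits$end
    hits$strand <- strand
    out <- rbind(out, hits)
  }
  out
}

#' Calibrate a model's reference score in genomic context
#'
#' [train_model()] records `s_ref` as the global alignment score of the
#' reference pre-miRNA against the model. The search itself scores
#' free-end-gap sub-hits inside genomic windows, where a flanking base can
#' occasionally improve on the reference's own end base (the consensus of
#' reference plus core orthologs need not peak at every reference base).
#' So that candidate score fractions are directly comparable to the
#' reference -- a self-search of the reference genome then yields fraction
#' exactly 1.0 at every annotated locus -- the reference score is
#' re-derived here by running the same scan over the annotated locus and
#' its flanks and keeping the best hit that overlaps the locus.
#'
#' @param model A `mirna_cm` model whose first training row is the
#'   reference pre-miRNA.
#' @param mirna One-row reference miRNA table entry (annotated locus).
#' @param genome Reference [genome_sequence()].
#' @param extension Flank length scanned on each side of the locus;
#'   matches the candidate-region extension of [search_params()].
#' @return The calibrated reference score (never below the trained
#'   `s_ref`).
#' @export
calibrate_reference_score <- function(model, mirna, genome,
                                      extension = 1000L) {
  chrom_len <- nchar(genome$seqs[[mirna$chrom]])
  region <- data.frame(chrom = mirna$chrom,
                       start = max(0L, mirna$start - extension),
                       end = min(chrom_len, mirna$end + extension),
                       stringsAsFactors = FALSE)
  hits <- scan_region_hits(model, genome, region,
                           min_keep = model$s_ref - 1e-9)
  if (is.null(hits) || nrow(hits) == 0) return(model$s_ref)
  ov <- hits$end > mirna$start & hits$start < mirna$end
  if (!any(ov)) return(model$s_ref)
  max(hits$score[ov], model$s_ref)
}

#' Targeted search for orthologs of one miRNA in a target genome
#'
#' Candidate regions are scanned with the trained model; hits reaching
#' `threshold * s_ref` are deduplicated (overlapping hits keep the higher
#' score) and confirmed by a reverse similarity search against the
#' reference genome. All confirmed hits are kept as co-orthologs, ranked
#' by score.
#'
#' @param model A `mirna_cm` model for this miRNA.
#' @param mirna One-row reference miRNA table entry.
#' @param target_genome Target [genome_sequence()].
#' @param ref_genome Reference [genome_sequence()].
#' @param params [search_params()].
#' @param blast [blast_params()].
#' @return Prediction data frame: `mirna_id`, `family_id`, `chrom`,
#'   `start`, `end`, `strand`, `sequence`, `bit_score`, `score_fraction`,
#'   `seed_identical`, `corank`. Zero rows mean "ortholog absent".
#' @export
search_orthologs <- function(model, mirna, target_genome, ref_genome,
                             params = search_params(),
                             blast = blast_params()) {
  empty <- data.frame(mirna_id = character(), family_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), bit_score = numeric(),
                      score_fraction = numeric(), seed_identical = logical(),
                      corank = integer(), stringsAsFactors = FALSE)
  regions <- candidate_regions(mirna, target_genome, params, blast,
                               model_length = model$L)
  if (nrow(regions) == 0) return(empty)
  min_keep <- params$threshold * model$s_ref
  hits <- NULL
  for (r in seq_len(nrow(regions))) {
    hits <- rbind(hits, scan_region_hits(model, target_genome,
                                         regions[r, ], min_keep))
  }
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  # deduplicate overlapping hits across regions: keep the best score
  hits <- hits[order(-hits$score, hits$start, hits$strand), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (a in seq_len(nrow(hits))) {
    if (!keep[a] || a == nrow(hits)) next
    for (b in (a + 1L):nrow(hits)) {
      if (!keep[b]) next
      if (hits$chrom[a] == hits$chrom[b] &&
          min(hits$end[a], hits$end[b]) -
            max(hits$start[a], hits$start[b]) > 0) {
        keep[b] <- FALSE
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  preds <- list()
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    seq <- extract_sequence(target_genome,
                            gi(h$chrom, h$start, h$end, h$strand))
    if (!confirm_by_reverse_search(seq, ref_genome, mirna, blast)) next
    preds[[length(preds) + 1L]] <- data.frame(
      mirna_id = mirna$mirna_id, family_id = mirna$family_id,
      chrom = h$chrom, start = h$start, end = h$end, strand = h$strand,
      sequence = seq, bit_score = h$score,
      score_fraction = h$score / model$s_ref,
      seed_identical = seed_identical(mirna, seq),
      corank = NA_integer_, stringsAsFactors = FALSE)
  }
  if (length(preds) == 0) return(empty)
  df <- do.call(rbind, preds)
  df <- df[order(-df$bit_score, df$start), , drop = FALSE]
  df$corank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Is the seed region of a prediction identical to the reference?
#'
#' The prediction is globally aligned to the reference pre-miRNA and the
#' seven nucleotides aligned opposite mature positions 2-8 are compared.
#' Returns `NA` ("unknown") when the miRNA lacks a mature annotation.
#'
#' @param mirna One-row miRNA table entry (with mature sub-annotation).
#' @param prediction_seq Predicted pre-miRNA sequence (transcribed
#'   orientation).
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
seed_identical <- function(mirna, prediction_seq) {
  if (is.na(mirna$mature_start) || is.na(mirna$mature_end)) {
    return(NA)
  }
  # mature offset within the transcribed pre-miRNA
  off <- if (mirna$strand == "+") {
    mirna$mature_start - mirna$start
  } else {
    mirna$end - mirna$mature_end
  }
  seed_pos <- off + 2:8   # 1-based positions 2-8 of the mature arm
  al <- global_align(mirna$sequence, prediction_seq)
  ra <- strsplit(al$a, "")[[1]]
  pa <- strsplit(al$b, "")[[1]]
  rp <- cumsum(ra != "-")
  cols <- match(seed_pos, rp)
  cols <- cols[!is.na(cols)]
  if (length(cols) != 7L) return(FALSE)
  all(pa[cols] != "-" & pa[cols] == ra[cols])
}
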