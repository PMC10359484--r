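#' Classify predictions of one family in one species
#'
#' Greedy, score-ranked matching against the gold-standard loci: a
#' prediction overlapping (>= 1 nt) an unmatched gold interval of the same
#' family is a true positive; predictions left unmatched are false
#' positives; gold intervals left unmatched are false negatives; a cell
#' with neither predictions nor gold entries contributes one true
#' negative.
#'
#' @param predictions Prediction data frame (may be empty), with `chrom`,
#'   `start`, `end` and (optionally) `bit_score` columns.
#' @param gold Gold-standard data frame (may be empty) with `chrom`,
#'   `start`, `end` columns.
#' @return Named list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
classify_cell <- function(predictions, gold) {
  np <- if (is.null(predictions)) 0L else nrow(predictions)
  ng <- if (is.null(gold)) 0L else nrow(gold)
  if (np == 0L && ng == 0L) return(list(TP = 0L, FP = 0L, FN = 0L, TN = 1L))
  if (np == 0L) return(list(TP = 0L, FP = 0L, FN = ng, TN = 0L))
  if (ng == 0L) return(list(TP = 0L, FP = np, FN = 0L, TN = 0L))
  if ("bit_score" %in% names(predictions)) {
    predictions <- predictions[order(-predictions$bit_score), , drop = FALSE]
  }
  matched_gold <- rep(FALSE, ng)
  tp <- 0L
  for (p in seq_len(np)) {
    hit <- FALSE
    for (g in seq_len(ng)) {
      if (matched_gold[g]) next
      if (predictions$chrom[p] == gold$chrom[g] &&
          min(predictions$end[p], gold$end[g]) -
            max(predictions$start[p], gold$start[g]) > 0) {
        matched_gold[g] <- TRUE
        hit <- TRUE
        break
      }
    }
    if (hit) tp <- tp + 1L
  }
  list(TP = tp, FP = np - tp, FN = sum(!matched_gold), TN = 0L)
}

#' Benchmark a prediction set against a gold standard
#'
#' Tallies confusion counts over every family x species cell.
#'
#' @param predictions Prediction data frame with `family_id` and `species`
#'   columns.
#' @param gold Gold-standard data frame (see [read_gold_standard()]).
#' @param families Character vector of all evaluated family ids.
#' @param species Character vector of all evaluated species.
#' @return List with `counts` (TP/FP/FN/TN) and `per_cell` (data frame).
#' @export
benchmark_predictions <- function(predictions, gold, families, species) {
  counts <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  cells <- list()
  for (sp in species) {
    for (fam in families) {
      p <- predictions[predictions$species == sp &
                         predictions$family_id == fam, , drop = FALSE]
      g <- gold[gold$species == sp & gold$family_id == fam, , drop = FALSE]
      cc <- classify_cell(p, g)
      counts <- counts + unlist(cc)
      cells[[length(cells) + 1L]] <- data.frame(
        species = sp, family_id = fam, TP = cc$TP, FP = cc$FP,
        FN = cc$FN, TN = cc$TN, stringsAsFactors = FALSE)
    }
  }
  list(counts = as.list(counts), per_cell = do.call(rbind, cells))
}

#' Benchmark metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FP+FN+TN)` and F1 `2*TP/(2*TP+FP+FN)`. A metric whose
#' denominator is zero is reported as `NA` (undefined).
#'
#' @param counts Named list or vector with `TP`, `FP`, `FN`, `TN`.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`, `f1`.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    accuracy = safe(tp + tn, tp + fp + fn + tn),
    f1 = safe(2 * tp, 2 * tp + fp + fn)
  )
}

#' Whole-genome-alignment ortholog call from an alignment block
#'
#' For each non-reference species row of a (MAF-style) alignment block,
#' the call is positive if the row's sequence covers at least 70% of the
#' reference miRNA locus, gaps excluded. The reference row defines the
#' column coordinate system.
#'
#' @param mirna_iv One-row interval of the reference miRNA (same assembly
#'   as the reference row).
#' @param block Data frame of block rows (see [read_maf_blocks()]); the
#'   `src` column holds species identifiers.
#' @param ref_species Identifier of the reference row.
#' @param min_coverage Minimum fraction of the locus covered (default
#'   0.7, inclusive).
#' @return Named logical vector over the non-reference species.
#' @export
wga_block_call <- function(mirna_iv, block, ref_species,
                           min_coverage = 0.7) {
  ref_row <- block[block$src == ref_species, , drop = FALSE]
  if (nrow(ref_row) == 0) stop("reference species row absent from block")
  ref_row <- ref_row[1, ]
  ref_chars <- strsplit(ref_row$text, "")[[1]]
  # genome position (0-based) of each block column on the reference row
  pos <- rep(NA_integer_, length(ref_chars))
  p <- ref_row$start
  for (i in seq_along(ref_chars)) {
    if (ref_chars[i] != "-") {
      pos[i] <- p
      p <- p + 1L
    }
  }
  in_locus <- !is.na(pos) & pos >= mirna_iv$start & pos < mirna_iv$end
  span_cols <- which(in_locus)
  locus_len <- mirna_iv$end - mirna_iv$start
  others <- block[block$src != ref_species, , drop = FALSE]
  out <- logical(nrow(others))
  names(out) <- others$src
  for (r in seq_len(nrow(others))) {
    chars <- strsplit(others$text[r], "")[[1]]
    covered <- sum(chars[span_cols] != "-")
    out[r] <- covered >= min_coverage * locus_len
  }
  out
}

#' Naive best-hit baseline
#'
#' Returns the best similarity hit of the reference pre-miRNA in the
#' target genome, unconditionally (no model threshold, no reverse
#' confirmation) -- the low-specificity baseline.
#'
#' @param mirna One-row miRNA table entry.
#' @param target_genome Target [genome_sequence()].
#' @param blast [blast_params()].
#' @return One-row hit data frame, or `NULL` if nothing aligns.
#' @export
naive_blast_call <- function(mirna, target_genome, blast = blast_params()) {
  best_hit(local_search(mirna$sequence, target_genome, blast))
}
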