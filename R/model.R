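#' Build the training alignment for a miRNA profile model
#'
#' Aligns the reference pre-miRNA together with its positional core
#' orthologs (built-in star alignment or mafft) and annotates the
#' alignment with a consensus secondary structure: the column-majority
#' consensus is folded (built-in maximum base-pairing folder or RNAfold)
#' and the resulting nested pair set is projected onto alignment columns.
#'
#' @param sequences Named character vector; the first element must be the
#'   reference pre-miRNA. A single sequence is allowed, with a warning that
#'   the model degenerates to the reference profile.
#' @param align_engine `"builtin"` or `"mafft"`.
#' @param fold_engine `"builtin"` or `"rnafold"`.
#' @param min_loop Minimum loop length for the built-in folder.
#' @return A list of class `training_alignment`: `msa` (character matrix,
#'   rows = sequences), `pairs` (two-column matrix of paired columns,
#'   i < j), `consensus` (consensus string), `ref_name`.
#' @export
build_training_alignment <- function(sequences,
                                     align_engine = c("builtin", "mafft"),
                                     fold_engine = c("builtin", "rnafold"),
                                     min_loop = 3L) {
  align_engine <- match.arg(align_engine)
  fold_engine <- match.arg(fold_engine)
  if (length(sequences) == 0) stop("no training sequences")
  if (is.null(names(sequences))) {
    names(sequences) <- c("reference",
                          paste0("seq", seq_along(sequences)[-1]))
  }
  if (length(sequences) == 1) {
    warning("single training sequence: model degenerates to the reference profile")
  }
  sequences <- toupper(chartr("Uu", "Tt", sequences))
  msa <- if (align_engine == "mafft" && length(sequences) > 1) {
    mafft_align(sequences)
  } else {
    star_align(sequences)
  }
  cons <- column_consensus(msa)
  nongap <- which(cons != "-")
  partner_sub <- fold_sequence(paste(cons[nongap], collapse = ""),
                               min_loop = min_loop, engine = fold_engine)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  for (p in seq_along(partner_sub)) {
    q <- partner_sub[p]
    if (!is.na(q) && q > p) {
      pairs <- rbind(pairs, c(nongap[p], nongap[q]))
    }
  }
  structure(list(msa = msa, pairs = pairs,
                 consensus = paste(cons, collapse = ""),
                 ref_name = rownames(msa)[1]),
            class = "training_alignment")
}

#' @export
print.training_alignment <- function(x, ...) {
  cat(sprintf("<training_alignment> %d sequences x %d columns, %d paired columns\n",
              nrow(x$msa), ncol(x$msa), 2L * nrow(x$pairs)))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

#' Train a miRNA sequence+structure profile model
#'
#' Fits per-column nucleotide log-odds emissions and, for each paired
#' column couple of the consensus structure, pairwise log-odds covariation
#' terms, from the training alignment with Laplace pseudocounts. The
#' reference maximum score `s_ref` (the score of the reference pre-miRNA
#' itself) is recorded; search hits are later accepted relative to it.
#'
#' With `m` alignment rows and column counts `c_i(a)` (rows gapped at a
#' column are excluded from its counts):
#' \deqn{e_i(a) = \log_2\frac{(c_i(a)+\alpha)/(m+4\alpha)}{1/4}}
#' \deqn{g_{ij}(a,b) = \log_2\frac{(c_{ij}(a,b)+\alpha)/(m+16\alpha)}
#'   {\frac{c_i(a)+\alpha}{m+4\alpha}\cdot\frac{c_j(b)+\alpha}{m+4\alpha}}}
#'
#' @param aln A [build_training_alignment()] result.
#' @param alpha Laplace pseudocount (default 1).
#' @param gap Linear gap penalty in bits used when scoring sequences
#'   against the model (default 2).
#' @param mirna_id Model identifier.
#' @return An object of class `mirna_cm`.
#' @export
train_model <- function(aln, alpha = 1, gap = 2.0, mirna_id = aln$ref_name) {
  msa <- aln$msa
  m <- nrow(msa)
  L <- ncol(msa)
  counts <- matrix(0, nrow = 4, ncol = L, dimnames = list(BASES, NULL))
  for (a in BASES) counts[a, ] <- colSums(msa == a)
  probs <- (counts + alpha) / (m + 4 * alpha)
  emis <- log2(probs / 0.25)
  pair_emis <- vector("list", nrow(aln$pairs))
  if (nrow(aln$pairs) > 0) {
    for (r in seq_len(nrow(aln$pairs))) {
      i <- aln$pairs[r, 1]; j <- aln$pairs[r, 2]
      cij <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
      ok <- msa[, i] %in% BASES & msa[, j] %in% BASES
      if (any(ok)) {
        tab <- table(factor(msa[ok, i], levels = BASES),
                     factor(msa[ok, j], levels = BASES))
        cij <- cij + as.matrix(tab)
      }
      pij <- (cij + alpha) / (m + 16 * alpha)
      pair_emis[[r]] <- log2(pij / (probs[, i] %o% probs[, j]))
    }
  }
  model <- structure(list(
    mirna_id = mirna_id, L = L, emis = emis, pairs = aln$pairs,
    pair_emis = pair_emis, gap = gap, nseq = m,
    consensus = aln$consensus, s_ref = NA_real_
  ), class = "mirna_cm")
  ref_seq <- paste(msa[1, msa[1, ] != "-"], collapse = "")
  model$s_ref <- score_sequence(model, ref_seq)
  if (!is.finite(model$s_ref) || model$s_ref <= 0) {
    warning(sprintf("model %s has non-positive reference score (%.2f)",
                    mirna_id, model$s_ref))
  }
  model
}

#' Score a sequence against a profile model
#'
#' Stage 1 globally aligns the sequence to the model columns, maximizing
#' the summed single-column emissions with a linear gap penalty; stage 2
#' adds the pairwise covariation term for every structural column pair
#' whose two columns are both matched to nucleotides.
#'
#' @param model A [train_model()] object.
#' @param seq Nucleotide string.
#' @return Score in bits.
#' @export
score_sequence <- function(model, seq) {
  if (is.null(seq) || !nzchar(seq)) stop("empty sequence")
  enc <- encode_dna(chartr("Uu", "Tt", toupper(seq)))
  al <- profile_align_cpp(enc, model$emis, model$gap, FALSE)
  al$score + pair_bonus(model, enc, al$cols)
}

# stage-2 pairwise covariation bonus given the column -> sequence-position
# assignment from stage 1 (0-based positions, -1 = gapped column)
pair_bonus <- function(model, enc, cols) {
  if (nrow(model$pairs) == 0) return(0)
  bonus <- 0
  for (r in seq_len(nrow(model$pairs))) {
    pi <- cols[model$pairs[r, 1]]; pj <- cols[model$pairs[r, 2]]
    if (pi < 0 || pj < 0) next
    a <- enc[pi + 1L]; b <- enc[pj + 1L]
    if (a < 0 || b < 0) next
    bonus <- bonus + model$pair_emis[[r]][a + 1L, b + 1L]
  }
  bonus
}

#' @export
print.mirna_cm <- function(x, ...) {
  cat(sprintf("<mirna_cm> %s: %d columns, %d base pairs, %d training sequences\n",
              x$mirna_id, x$L, nrow(x$pairs), x$nseq))
  cat(sprintf("  reference score: %.2f bits (acceptance at fraction of this)\n",
              x$s_ref))
  invisible(x)
}

#' @export
summary.mirna_cm <- function(object, ...) {
  ic <- colSums(2^object$emis * 0.25 * object$emis) # information content/col
  res <- list(mirna_id = object$mirna_id, L = object$L,
              nseq = object$nseq, n_pairs = nrow(object$pairs),
              s_ref = object$s_ref, mean_info = mean(ic))
  class(res) <- "summary.mirna_cm"
  res
}

#' @export
print.summary.mirna_cm <- function(x, ...) {
  cat(sprintf("Profile model %s\n", x$mirna_id))
  cat(sprintf("  columns: %d   structural pairs: %d   training sequences: %d\n",
              x$L, x$n_pairs, x$nseq))
  cat(sprintf("  reference score: %.2f bits   mean column information: %.2f bits\n",
              x$s_ref, x$mean_info))
  invisible(x)
}

#' @export
coef.mirna_cm <- function(object, ...) object$emis

#' Predict method: score sequences against the model
#'
#' @param object A `mirna_cm` model.
#' @param newdata Character vector of sequences.
#' @param type `"bits"` for absolute scores, `"fraction"` for the score as
#'   a fraction of the reference score.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.mirna_cm <- function(object, newdata,
                             type = c("bits", "fraction"), ...) {
  type <- match.arg(type)
  sc <- vapply(newdata, function(s) score_sequence(object, s), numeric(1))
  if (type == "fraction") sc <- sc / object$s_ref
  unname(sc)
}

#' Serialize a profile model to a plain-text file
#'
#' Key-value header followed by the emission matrix and per-pair
#' covariation matrices; [read_cm()] restores the model bit-exactly.
#'
#' @param model A `mirna_cm` object.
#' @param path Output path.
#' @export
write_cm <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    paste0("id\t", model$mirna_id),
    paste0("L\t", model$L),
    paste0("nseq\t", model$nseq),
    paste0("gap\t", num(model$gap)),
    paste0("s_ref\t", num(model$s_ref)),
    paste0("consensus\t", model$consensus),
    paste0("npairs\t", nrow(model$pairs))
  ), con)
  writeLines("EMIS", con)
  utils::write.table(format(model$emis, digits = 17, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  if (nrow(model$pairs) > 0) {
    for (r in seq_len(nrow(model$pairs))) {
      writeLines(sprintf("PAIR\t%d\t%d", model$pairs[r, 1], model$pairs[r, 2]),
                 con)
      utils::write.table(format(model$pair_emis[[r]], digits = 17,
                                scientific = TRUE),
                         con, sep = "\t", quote = FALSE,
                         row.names = TRUE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_cm
#' @export
read_cm <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[1:7], "\t")
  hdr <- stats::setNames(vapply(kv, `[`, character(1), 2),
                         vapply(kv, `[`, character(1), 1))
  L <- as.integer(hdr[["L"]])
  npairs <- as.integer(hdr[["npairs"]])
  stopifnot(lines[8] == "EMIS")
  parse_mat <- function(rows, ncols) {
    m <- do.call(rbind, lapply(rows, function(ln) {
      as.numeric(strsplit(ln, "\t")[[1]][-1])
    }))
    rownames(m) <- BASES
    m
  }
  emis <- parse_mat(lines[9:12], L)
  pos <- 13L
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  pair_emis <- list()
  for (r in seq_len(npairs)) {
    f <- strsplit(lines[pos], "\t")[[1]]
    pairs <- rbind(pairs, as.integer(f[2:3]))
    pm <- parse_mat(lines[(pos + 1L):(pos + 4L)], 4)
    colnames(pm) <- BASES
    pair_emis[[r]] <- pm
    pos <- pos + 5L
  }
  structure(list(
    mirna_id = hdr[["id"]], L = L, emis = emis, pairs = pairs,
    pair_emis = pair_emis, gap = as.numeric(hdr[["gap"]]),
    nseq = as.integer(hdr[["nseq"]]), consensus = hdr[["consensus"]],
    s_ref = as.numeric(hdr[["s_ref"]])
  ), class = "mirna_cm")
}

#' Write a training alignment as Stockholm
#'
#' Includes the consensus structure as a `#=GC SS_cons` dot-bracket line.
#'
#' @param aln A `training_alignment`.
#' @param path Output path.
#' @export
write_stockholm <- function(aln, path) {
  partner <- rep(NA_integer_, ncol(aln$msa))
  if (nrow(aln$pairs) > 0) {
    partner[aln$pairs[, 1]] <- aln$pairs[, 2]
    partner[aln$pairs[, 2]] <- aln$pairs[, 1]
  }
  rows <- apply(aln$msa, 1, paste, collapse = "")
  w <- max(nchar(rownames(aln$msa)), nchar("#=GC SS_cons"))
  writeLines(c(
    "# STOCKHOLM 1.0",
    sprintf("%-*s %s", w, rownames(aln$msa), rows),
    sprintf("%-*s %s", w, "#=GC SS_cons", partners_to_dotbracket(partner)),
    "//"
  ), path)
  invisible(path)
}

#' Train profile models for every reference miRNA
#'
#' For each miRNA in the reference table, positional orthologs are
#' collected from all core species ([collect_positional_ortholog()]), the
#' training alignment is built and the model trained.
#'
#' @param ref A reference bundle: list with `genome`, `annotation`,
#'   `mirnas` (miRNA table).
#' @param cores Named list of core bundles, each with `genome`,
#'   `annotation`, `orthologs`.
#' @param params [synteny_params()].
#' @param search_params [blast_params()].
#' @param align_engine,fold_engine Backends for
#'   [build_training_alignment()].
#' @return A list with `models` (named list of `mirna_cm`) and `report`
#'   (data frame: `mirna_id`, `n_core_orthologs`). Each model's reference
#'   score is calibrated in genomic context with
#'   [calibrate_reference_score()].
#' @export
create_models <- function(ref, cores, params = synteny_params(),
                          search_params = blast_params(),
                          align_engine = "builtin",
                          fold_engine = "builtin") {
  models <- list()
  report <- list()
  for (r in seq_len(nrow(ref$mirnas))) {
    mirna <- ref$mirnas[r, ]
    orths <- list()
    for (cs in names(cores)) {
      seq <- tryCatch(
        collect_positional_ortholog(mirna, ref$annotation, ref$genome,
                                    cores[[cs]], params, search_params),
        error = function(e) stop(sprintf("miRNA %s, core %s: %s",
                                         mirna$mirna_id, cs,
                                         conditionMessage(e))))
      if (!is.null(seq)) orths[[cs]] <- seq
    }
    seqs <- c(stats::setNames(mirna$sequence, mirna$mirna_id), unlist(orths))
    aln <- suppressWarnings(
      build_training_alignment(seqs, align_engine = align_engine,
                               fold_engine = fold_engine))
    model <- train_model(aln, mirna_id = mirna$mirna_id)
    model$s_ref <- calibrate_reference_score(model, mirna, ref$genome)
    models[[mirna$mirna_id]] <- model
    report[[length(report) + 1L]] <- data.frame(
      mirna_id = mirna$mirna_id, n_core_orthologs = length(orths),
      stringsAsFactors = FALSE)
  }
  list(models = models, report = do.call(rbind, report))
}
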