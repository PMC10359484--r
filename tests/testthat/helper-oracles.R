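# Independent test oracles. These deliberately re-derive results by
# exhaustive enumeration rather than calling the package's own search
# logic, so the tests are a genuine second route to the same answer.

# Brute-force shared-syntenic-region oracle: enumerate every anchor pair,
# keep qualifying ones, and pick the nearest by (combined rank, upstream
# rank). Intervening genes are counted on the per-chromosome start order.
oracle_shared_region <- function(context, core_ann, orth, k, flank) {
  ann <- core_ann[order(core_ann$chrom, core_ann$start), , drop = FALSE]
  loc <- function(gid) {
    i <- which(ann$gene_id == gid)
    if (length(i) > 0) i[1] else NA_integer_
  }
  if (context$kind == "intragenic" && !is.na(context$host) &&
      context$host %in% names(orth)) {
    i <- loc(orth[[context$host]])
    if (!is.na(i)) {
      return(list(chrom = ann$chrom[i],
                  start = max(0L, ann$start[i] - flank),
                  end = ann$end[i] + flank))
    }
  }
  up <- context$up; down <- context$down
  best <- NULL; best_key <- c(Inf, Inf)
  for (u in seq_along(up)) {
    for (d in seq_along(down)) {
      if (!(up[u] %in% names(orth)) || !(down[d] %in% names(orth))) next
      i <- loc(orth[[up[u]]]); j <- loc(orth[[down[d]]])
      if (is.na(i) || is.na(j)) next
      if (ann$chrom[i] != ann$chrom[j]) next
      same <- which(ann$chrom == ann$chrom[i])
      if (abs(match(i, same) - match(j, same)) - 1L > k) next
      key <- c(u + d, u)
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_key <- key
        best <- list(chrom = ann$chrom[i],
                     start = max(0L, min(ann$start[i], ann$start[j]) - flank),
                     end = max(ann$end[i], ann$end[j]) + flank)
      }
    }
  }
  best
}

# Random synteny scenario: a reference chromosome with up to 30 ordered
# genes and one planted miRNA, and a core species whose gene order is a
# random permutation spread over 1-3 chromosomes with incomplete ortholog
# mapping.
random_synteny_case <- function() {
  m <- sample(4:30, 1)
  ref_ann <- make_annotation(sprintf("g%02d", seq_len(m)), "rchr",
                             start = (seq_len(m) - 1L) * 1000L + 100L,
                             end = (seq_len(m) - 1L) * 1000L + 600L)
  if (stats::runif(1) < 0.3) {                    # intragenic miRNA
    i <- sample(m, 1)
    mir <- data.frame(chrom = "rchr", start = ref_ann$start[i] + 10L,
                      end = ref_ann$start[i] + 72L, stringsAsFactors = FALSE)
  } else {                                        # intergenic miRNA
    i <- sample(m - 1L, 1)
    mir <- data.frame(chrom = "rchr", start = ref_ann$end[i] + 100L,
                      end = ref_ann$end[i] + 162L, stringsAsFactors = FALSE)
  }
  perm <- sample(m)
  chroms <- sample(paste0("cchr", seq_len(sample(1:3, 1))), m, replace = TRUE)
  core_start <- integer(m)
  for (ch in unique(chroms)) {
    on_ch <- which(chroms == ch)
    core_start[on_ch] <- (seq_along(on_ch) - 1L) * 1000L + 100L
  }
  core_ann <- make_annotation(paste0("c_", ref_ann$gene_id[perm]),
                              chroms, core_start, core_start + 500L)
  kept <- stats::runif(m) < 0.7
  orth <- stats::setNames(paste0("c_", ref_ann$gene_id[kept]),
                          ref_ann$gene_id[kept])
  list(mirna = mir, ref_ann = ref_ann, core_ann = core_ann, orthologs = orth)
}

# Exhaustive scoring oracle: enumerate every monotone assignment of model
# columns to sequence positions (both strictly increasing), score each one
# directly from the emission matrix and gap penalty, and add the pairwise
# covariation bonus of the unique best assignment. Feasible for L <= 8 and
# short sequences only.
oracle_model_score <- function(model, enc) {
  L <- model$L; n <- length(enc)
  best <- -Inf; best_cols <- NULL
  for (k in 0:min(L, n)) {
    col_sets <- if (k == 0) matrix(integer(0), 0, 1) else utils::combn(L, k)
    pos_sets <- if (k == 0) matrix(integer(0), 0, 1) else utils::combn(n, k)
    for (ci in seq_len(ncol(col_sets))) {
      cols <- col_sets[, ci]
      for (pi in seq_len(ncol(pos_sets))) {
        poss <- pos_sets[, pi]
        s <- sum(model$emis[cbind(enc[poss] + 1L, cols)]) -
          model$gap * ((L - k) + (n - k))
        if (s > best) {
          best <- s
          bc <- rep(-1L, L); bc[cols] <- poss - 1L
          best_cols <- bc
        }
      }
    }
  }
  bonus <- 0
  if (nrow(model$pairs) > 0) {
    for (r in seq_len(nrow(model$pairs))) {
      p1 <- best_cols[model$pairs[r, 1]]; p2 <- best_cols[model$pairs[r, 2]]
      if (p1 >= 0 && p2 >= 0) {
        bonus <- bonus + model$pair_emis[[r]][enc[p1 + 1L] + 1L,
                                              enc[p2 + 1L] + 1L]
      }
    }
  }
  best + bonus
}

# Random profile model with continuous emissions (so the best assignment is
# almost surely unique) and optional structural pairs.
random_profile_model <- function(L, n_pairs = sample(0:(L %/% 3), 1)) {
  bases <- c("A", "C", "G", "T")
  emis <- matrix(stats::runif(4 * L, -2, 2), 4, L,
                 dimnames = list(bases, NULL))
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  pair_emis <- list()
  avail <- seq_len(L)
  for (r in seq_len(n_pairs)) {
    if (length(avail) < 2) break
    ij <- sort(sample(avail, 2))
    avail <- setdiff(avail, ij)
    pairs <- rbind(pairs, ij)
    pair_emis[[nrow(pairs)]] <- matrix(stats::runif(16, -2, 2), 4, 4,
                                       dimnames = list(bases, bases))
  }
  structure(list(mirna_id = "rand", L = L, emis = emis, pairs = pairs,
                 pair_emis = pair_emis, gap = 2, nseq = 1,
                 consensus = strrep("A", L), s_ref = 1),
            class = "mirna_cm")
}

# Exhaustive maximum base-pairing oracle: enumerate every non-crossing set
# of complementary pairs (Watson-Crick plus G:T wobble) respecting the
# minimum loop length, and return the maximum pair count. Exponential;
# only for very short sequences.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  enc <- encode_dna(seq)
  can_pair <- function(a, b) {
    (a + b == 3L) || (a + b == 5L && (a == 2L || b == 2L))
  }
  count <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- count(i, j - 1L)               # j unpaired
    for (t in i:(j - min_loop - 1L)) {     # j paired with t
      if (can_pair(enc[t], enc[j])) {
        left <- if (t - 1L >= i) count(i, t - 1L) else 0L
        best <- max(best, left + 1L + count(t + 1L, j - 1L))
      }
    }
    best
  }
  n <- length(enc)
  if (n < min_loop + 2L) return(0L)
  count(1L, n)
}
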