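#' Build a phylogenetic profile matrix from predictions
#'
#' Gene-level matrix of co-ortholog counts (rows = miRNA genes, columns =
#' species; 0 = absent) plus a parallel seed-status matrix
#' (`"identical"`, `"changed"` or `"unknown"`; `NA` for absent cells).
#' Rows for miRNAs absent everywhere are preserved.
#'
#' @param predictions Prediction data frame with `mirna_id`, `family_id`,
#'   `species`, `corank`, `seed_identical` columns.
#' @param mirnas Reference miRNA table (defines the row universe).
#' @param species Character vector of species (defines the column
#'   universe).
#' @return A list of class `profile_matrix`: `counts` (integer matrix),
#'   `seed` (character matrix), `family` (named vector mirna -> family),
#'   `level` (`"gene"` or `"family"`).
#' @export
build_profiles <- function(predictions, mirnas, species) {
  ids <- mirnas$mirna_id
  counts <- matrix(0L, nrow = length(ids), ncol = length(species),
                   dimnames = list(ids, species))
  seed <- matrix(NA_character_, nrow = length(ids), ncol = length(species),
                 dimnames = list(ids, species))
  if (nrow(predictions) > 0) {
    for (r in seq_len(nrow(predictions))) {
      p <- predictions[r, ]
      if (!p$mirna_id %in% ids || !p$species %in% species) next
      counts[p$mirna_id, p$species] <- counts[p$mirna_id, p$species] + 1L
      status <- if (is.na(p$seed_identical)) "unknown"
                else if (p$seed_identical) "identical" else "changed"
      prev <- seed[p$mirna_id, p$species]
      if (is.na(prev) || (prev != "identical" && status == "identical")) {
        seed[p$mirna_id, p$species] <- status
      }
    }
  }
  structure(list(counts = counts, seed = seed,
                 family = stats::setNames(mirnas$family_id, mirnas$mirna_id),
                 level = "gene"),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s level: %d x %d, %d non-empty cells\n",
              x$level, nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Collapse a gene-level profile to the family level
#'
#' Family counts are the sums over member genes; family seed status is
#' `"identical"` if any member is identical.
#'
#' @param pm A gene-level [build_profiles()] matrix.
#' @return A family-level `profile_matrix`.
#' @export
collapse_to_family <- function(pm) {
  stopifnot(pm$level == "gene")
  fams <- unique(unname(pm$family))
  counts <- matrix(0L, nrow = length(fams), ncol = ncol(pm$counts),
                   dimnames = list(fams, colnames(pm$counts)))
  seed <- matrix(NA_character_, nrow = length(fams), ncol = ncol(pm$counts),
                 dimnames = list(fams, colnames(pm$counts)))
  for (fam in fams) {
    members <- names(pm$family)[pm$family == fam]
    counts[fam, ] <- colSums(pm$counts[members, , drop = FALSE])
    for (sp in colnames(pm$counts)) {
      st <- pm$seed[members, sp]
      st <- st[!is.na(st)]
      if (length(st) == 0) next
      seed[fam, sp] <- if (any(st == "identical")) "identical"
                       else if (any(st == "changed")) "changed" else "unknown"
    }
  }
  structure(list(counts = counts, seed = seed,
                 family = stats::setNames(fams, fams), level = "family"),
            class = "profile_matrix")
}

#' Date the evolutionary origin of a miRNA family
#'
#' The family origin is the last common ancestor of the reference species
#' and all species carrying at least one ortholog.
#'
#' @param counts Named integer vector (species -> co-ortholog count) for
#'   one family, or one row of a family-level profile matrix.
#' @param tree A rooted `phylo` tree whose tips cover the profile species.
#' @param ref_species Reference species tip label.
#' @return List with `node` (ape node number; a tip number if the family
#'   is reference-specific) and `label` (tip or node label, if present).
#' @export
date_family_origin <- function(counts, tree, ref_species) {
  carriers <- union(ref_species, names(counts)[counts > 0])
  if (!all(carriers %in% tree$tip.label)) {
    stop("profile species missing from tree")
  }
  if (length(carriers) == 1L) {
    node <- which(tree$tip.label == carriers)
    return(list(node = node, label = carriers))
  }
  node <- ape::getMRCA(tree, carriers)
  label <- if (!is.null(tree$node.label)) {
    tree$node.label[node - ape::Ntip(tree)]
  } else {
    NA_character_
  }
  list(node = node, label = label)
}

# tip labels descending from a node (the node itself if it is a tip)
node_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Fraction of missing data in a profile matrix
#'
#' A cell is missing if the family is absent from a species that
#' diversified after the family's origin; only species descending from a
#' family's origin node are eligible for that family.
#'
#' @param pm Family-level [profile_matrix].
#' @param tree Rooted `phylo` tree.
#' @param ref_species Reference species tip label.
#' @return Fraction in \[0, 1\]: missing eligible cells / eligible cells.
#' @export
missing_data_fraction <- function(pm, tree, ref_species) {
  eligible <- 0L
  missing <- 0L
  for (fam in rownames(pm$counts)) {
    row <- pm$counts[fam, ]
    if (all(row == 0)) next
    origin <- date_family_origin(row, tree, ref_species)
    tips <- intersect(node_tips(tree, origin$node), colnames(pm$counts))
    eligible <- eligible + length(tips)
    missing <- missing + sum(row[tips] == 0)
  }
  if (eligible == 0L) return(0)
  missing / eligible
}

#' Co-ortholog count spectrum of one species
#'
#' Among the miRNAs represented in the species (count >= 1), the fractions
#' with exactly 1, 2, 3, or 4-and-more co-orthologs. Lineage-specific
#' whole-genome duplications surface as a high fraction of miRNAs in the
#' two-or-more classes.
#'
#' @param pm Gene-level [profile_matrix].
#' @param species One species (column) name.
#' @return Named numeric vector `c("1", "2", "3", ">=4")`, summing to 1
#'   (all `NaN` if the species carries nothing).
#' @export
co_ortholog_spectrum <- function(pm, species) {
  if (!species %in% colnames(pm$counts)) {
    stop(sprintf("species '%s' absent from profile matrix", species))
  }
  v <- pm$counts[, species]
  v <- v[v >= 1L]
  bins <- c(sum(v == 1L), sum(v == 2L), sum(v == 3L), sum(v >= 4L))
  stats::setNames(bins / length(v), c("1", "2", "3", ">=4"))
}

#' Assemble a phylogenomic supermatrix from per-miRNA ortholog sets
#'
#' Each miRNA's orthologs (one sequence per species, the rank-1
#' co-ortholog) are aligned; species missing a miRNA are filled with
#' all-gap rows; the alignments are concatenated; columns with more than
#' 50% gaps are removed; species represented in fewer than
#' `min_representation` of the miRNAs are dropped.
#'
#' @param ortholog_sets Named list (miRNA id -> named character vector of
#'   species -> sequence). The reference sequence should come first within
#'   each set so the built-in star alignment centers on it.
#' @param species Character vector of species to include as rows.
#' @param min_representation Minimum fraction of miRNAs a species must be
#'   represented in (default 0.2).
#' @param max_gap_fraction Columns with a gap fraction strictly above this
#'   are removed (default 0.5).
#' @param align_engine Alignment backend (see
#'   [build_training_alignment()]).
#' @return List with `matrix` (named character vector of concatenated,
#'   filtered rows), `partitions` (data frame: `mirna_id`, `start`, `end`,
#'   1-based columns in the filtered matrix), `dropped_species`.
#' @export
build_supermatrix <- function(ortholog_sets, species,
                              min_representation = 0.2,
                              max_gap_fraction = 0.5,
                              align_engine = "builtin") {
  if (length(species) < 2) stop("need at least two species")
  rep_frac <- vapply(species, function(sp) {
    mean(vapply(ortholog_sets, function(s) sp %in% names(s), logical(1)))
  }, numeric(1))
  dropped <- species[rep_frac < min_representation]
  species <- setdiff(species, dropped)
  if (length(species) < 2) stop("fewer than two species after filtering")
  blocks <- list()
  parts <- list()
  pos <- 0L
  for (mid in names(ortholog_sets)) {
    seqs <- ortholog_sets[[mid]]
    seqs <- seqs[names(seqs) %in% species]
    if (length(seqs) == 0) next
    msa <- if (length(seqs) == 1) {
      matrix(strsplit(seqs[[1]], "")[[1]], nrow = 1,
             dimnames = list(names(seqs), NULL))
    } else if (align_engine == "mafft") {
      mafft_align(seqs)
    } else {
      star_align(seqs)
    }
    width <- ncol(msa)
    block <- matrix("-", nrow = length(species), ncol = width,
                    dimnames = list(species, NULL))
    block[rownames(msa), ] <- msa
    # column gap filter (strictly more than the allowed fraction)
    gap_frac <- colMeans(block == "-")
    keep <- gap_frac <= max_gap_fraction
    block <- block[, keep, drop = FALSE]
    if (ncol(block) == 0) next
    blocks[[mid]] <- block
    parts[[mid]] <- data.frame(mirna_id = mid, start = pos + 1L,
                               end = pos + ncol(block),
                               stringsAsFactors = FALSE)
    pos <- pos + ncol(block)
  }
  full <- do.call(cbind, blocks)
  rows <- apply(full, 1, paste, collapse = "")
  list(matrix = rows,
       partitions = do.call(rbind, c(parts, list(make.row.names = FALSE))),
       dropped_species = dropped)
}

#' Write a supermatrix as FASTA, relaxed PHYLIP and a partition table
#'
#' @param sm A [build_supermatrix()] result.
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.phy` and `<prefix>.partitions.tsv`.
#' @export
write_supermatrix <- function(sm, prefix) {
  fa <- paste0(prefix, ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(sm$matrix)),
                             unname(sm$matrix))), fa)
  phy <- paste0(prefix, ".phy")
  writeLines(c(sprintf("%d %d", length(sm$matrix), nchar(sm$matrix[[1]])),
               sprintf("%s  %s", names(sm$matrix), unname(sm$matrix))), phy)
  utils::write.table(sm$partitions, paste0(prefix, ".partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write a profile matrix as long-format TSV
#'
#' One row per non-empty cell (plus explicit zero rows if
#' `keep_absent = TRUE`), compatible with phylogenetic-profile viewers.
#'
#' @param pm A [profile_matrix].
#' @param path Output path.
#' @param keep_absent Write zero-count cells too.
#' @export
write_profile_tsv <- function(pm, path, keep_absent = FALSE) {
  rows <- list()
  for (id in rownames(pm$counts)) {
    for (sp in colnames(pm$counts)) {
      n <- pm$counts[id, sp]
      if (n == 0L && !keep_absent) next
      rows[[length(rows) + 1L]] <- data.frame(
        geneID = id, ncbiID = sp, orthoID = if (n > 0L)
          paste0(id, "|", sp) else NA_character_,
        copies = n, seed = pm$seed[id, sp], stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
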