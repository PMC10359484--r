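#' Search many target species with a set of trained models
#'
#' Runs [search_orthologs()] for every model in every target genome and
#' binds the predictions with a `species` column. Output rows are ordered
#' by species, then miRNA id, then co-ortholog rank, so repeated runs are
#' comparable line by line.
#'
#' @param models Named list of `mirna_cm` models (as from
#'   [create_models()]).
#' @param mirnas Reference miRNA table.
#' @param targets Named list of target [genome_sequence()] objects
#'   (species -> genome).
#' @param ref_genome Reference [genome_sequence()] (for reverse
#'   confirmation).
#' @param params [search_params()].
#' @param blast [blast_params()].
#' @return Prediction data frame with a leading `species` column.
#' @export
search_species <- function(models, mirnas, targets, ref_genome,
                           params = search_params(),
                           blast = blast_params()) {
  out <- list()
  for (sp in names(targets)) {
    for (mid in names(models)) {
      mirna <- mirnas[mirnas$mirna_id == mid, , drop = FALSE]
      if (nrow(mirna) != 1) {
        stop(sprintf("model '%s' has no unique miRNA table entry", mid))
      }
      preds <- search_orthologs(models[[mid]], mirna, targets[[sp]],
                                ref_genome, params, blast)
      if (nrow(preds) > 0) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(species = sp, stringsAsFactors = FALSE), preds)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(species = character(), mirna_id = character(),
                      family_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      bit_score = numeric(), score_fraction = numeric(),
                      seed_identical = logical(), corank = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$species, df$mirna_id, df$corank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Run the full homology-search pipeline on a simulated clade
#'
#' Trains one profile model per reference miRNA from the simulated core
#' species, searches every non-reference species, and benchmarks the
#' predictions against the simulation's ground truth.
#'
#' @param sim An [evolve_clade()] result.
#' @param params [search_params()].
#' @param blast [blast_params()].
#' @param synteny [synteny_params()].
#' @param target_species Species to search (default: all non-reference
#'   tips).
#' @return List with `models`, `model_report`, `predictions`, `benchmark`
#'   (confusion counts and per-cell table) and `metrics`.
#' @export
run_pipeline <- function(sim, params = search_params(),
                         blast = blast_params(),
                         synteny = synteny_params(),
                         target_species = NULL) {
  ref <- sim_reference_bundle(sim)
  cores <- sim_core_bundles(sim)
  trained <- create_models(ref, cores, params = synteny,
                           search_params = blast)
  if (is.null(target_species)) {
    target_species <- setdiff(sim$tree$tip.label, sim$ref_species)
  }
  targets <- lapply(sim$species[target_species], `[[`, "genome")
  predictions <- search_species(trained$models, ref$mirnas, targets,
                                ref$genome, params, blast)
  gold <- sim$gold[sim$gold$species %in% target_species, , drop = FALSE]
  bench <- benchmark_predictions(predictions, gold,
                                 families = unique(ref$mirnas$family_id),
                                 species = target_species)
  list(models = trained$models, model_report = trained$report,
       predictions = predictions, benchmark = bench,
       metrics = metrics(bench$counts))
}

#' Region classes of a simulated reference genome
#'
#' Builds the seven diversity-analysis region classes from a simulated
#' clade's reference bundle: the five miRNA sub-regions plus `CDS` (genes
#' without an embedded miRNA, so the classes stay disjoint) and `lncRNA`
#' (intergenic segments sampled away from miRNA loci, serving as the
#' neutral non-coding comparison class).
#'
#' @param sim An [evolve_clade()] result.
#' @param n_lnc Number of lncRNA surrogate intervals.
#' @param lnc_len Length of each lncRNA interval (nt).
#' @return Named list of [region_class()] objects.
#' @export
reference_region_classes <- function(sim, n_lnc = 50L, lnc_len = 200L) {
  ref <- sim_reference_bundle(sim)
  classes <- mirna_region_classes(ref$mirnas)
  ann <- ref$annotation
  # CDS: genes that do not host a miRNA (keeps the classes disjoint)
  host <- character(0)
  for (r in seq_len(nrow(ref$mirnas))) {
    m <- ref$mirnas[r, ]
    inside <- ann$chrom == m$chrom & ann$start <= m$start & ann$end >= m$end
    host <- c(host, ann$gene_id[inside])
  }
  cds <- ann[!ann$gene_id %in% host, c("chrom", "start", "end")]
  classes[["CDS"]] <- region_class("CDS", cds)
  # lncRNA surrogates: intergenic stretches clear of genes and miRNA loci
  occupied <- rbind(
    ann[, c("chrom", "start", "end")],
    data.frame(chrom = ref$mirnas$chrom,
               start = pmin(ref$mirnas$flank5_start, ref$mirnas$flank3_start),
               end = pmax(ref$mirnas$flank5_end, ref$mirnas$flank3_end)))
  occupied <- merge_intervals(occupied)
  lnc <- list()
  for (chrom in names(ref$genome$seqs)) {
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    occ <- occ[order(occ$start), , drop = FALSE]
    gaps_start <- c(0L, occ$end)
    gaps_end <- c(occ$start, ref$genome$lengths[[chrom]])
    ok <- gaps_end - gaps_start >= lnc_len + 20L
    if (!any(ok)) next
    lnc[[chrom]] <- data.frame(
      chrom = chrom, start = gaps_start[ok] + 10L,
      end = gaps_start[ok] + 10L + lnc_len, stringsAsFactors = FALSE)
  }
  lnc <- do.call(rbind, lnc)
  if (is.null(lnc) || nrow(lnc) == 0) stop("no intergenic room for lncRNA surrogates")
  lnc <- lnc[seq_len(min(n_lnc, nrow(lnc))), , drop = FALSE]
  classes[["lncRNA"]] <- region_class("lncRNA", lnc)
  classes
}
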