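#' Microsynteny parameters
#'
#' @param k Maximum number of protein-coding genes allowed between the two
#'   anchor orthologs for a core region to count as shared syntenic
#'   (default 3).
#' @param n Maximum number of additional flanking genes considered as
#'   alternative anchors on each side (default 1).
#' @param flank Flank (nt) added to each side of the shared syntenic span,
#'   so hairpins at anchor edges are not clipped (default 100).
#' @return A list of class `synteny_params`.
#' @export
synteny_params <- function(k = 3L, n = 1L, flank = 100L) {
  stopifnot(k >= 0, n >= 0, flank >= 0)
  structure(list(k = as.integer(k), n = as.integer(n),
                 flank = as.integer(flank)),
            class = "synteny_params")
}

#' Classify the genomic context of a reference miRNA
#'
#' A miRNA is intragenic if a protein-coding gene interval fully contains
#' its pre-miRNA interval (the gene becomes the host); otherwise it is
#' intergenic and the nearest genes on each side (plus up to `n` further
#' genes per side, nearest first) become candidate syntenic anchors.
#' Flanking anchors are also recorded for intragenic miRNAs so the search
#' can fall back to intergenic logic when the host gene has no ortholog.
#'
#' @param mirna One-row miRNA table entry.
#' @param annotation Gene annotation data frame (see
#'   [read_gene_annotation()]).
#' @param params [synteny_params()].
#' @return A list of class `mirna_context` with elements `kind`
#'   (`"intragenic"` or `"intergenic"`), `host` (gene id or `NA`),
#'   `up`/`down` (anchor gene ids, nearest first).
#' @export
classify_context <- function(mirna, annotation, params = synteny_params()) {
  genes <- annotation[annotation$chrom == mirna$chrom, , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  host <- NA_character_
  contains <- genes$start <= mirna$start & genes$end >= mirna$end
  if (any(contains)) host <- genes$gene_id[which(contains)[1]]
  flank_genes <- genes[is.na(host) | genes$gene_id != host, , drop = FALSE]
  up <- flank_genes[flank_genes$end <= mirna$start, , drop = FALSE]
  down <- flank_genes[flank_genes$start >= mirna$end, , drop = FALSE]
  n_anch <- params$n + 1L
  up_ids <- rev(up$gene_id)            # nearest first
  down_ids <- down$gene_id
  structure(list(
    kind = if (is.na(host)) "intergenic" else "intragenic",
    host = host,
    up = utils::head(up_ids, n_anch),
    down = utils::head(down_ids, n_anch)
  ), class = "mirna_context")
}

#' Locate the shared syntenic region in a core species
#'
#' For intragenic miRNAs the region is the locus of the host gene's
#' ortholog; if the host has no ortholog, the intergenic logic is used.
#' For intergenic miRNAs, anchor pairs are tried nearest first; a pair
#' qualifies if both anchors have orthologs on the same core chromosome
#' with at most `k` genes between them. The returned span covers both
#' anchor genes, extended by `flank` nt per side (clipped at 0; the upper
#' bound is clipped against the genome at extraction time).
#'
#' @param context A [classify_context()] result.
#' @param core_annotation Gene annotation of the core species.
#' @param orthologs Named character vector (reference gene id -> core gene
#'   id), see [read_ortholog_table()].
#' @param params [synteny_params()].
#' @return A one-row interval data frame, or `NULL` if no anchor pair
#'   qualifies.
#' @export
shared_syntenic_region <- function(context, core_annotation, orthologs,
                                   params = synteny_params()) {
  core_annotation <- sort_annotation(core_annotation)
  locate <- function(gid) {
    idx <- which(core_annotation$gene_id == gid)
    if (length(idx) == 0) NULL else idx[1]
  }
  if (context$kind == "intragenic" && !is.na(context$host) &&
      context$host %in% names(orthologs)) {
    idx <- locate(orthologs[[context$host]])
    if (!is.null(idx)) {
      g <- core_annotation[idx, ]
      return(gi(g$chrom, max(0L, g$start - params$flank),
                g$end + params$flank))
    }
  }
  # intergenic logic (also the fallback for unmapped hosts)
  up <- context$up; down <- context$down
  if (length(up) == 0 || length(down) == 0) return(NULL)
  # order pairs nearest first: by combined rank, then upstream rank
  pairs <- expand.grid(u = seq_along(up), d = seq_along(down))
  pairs <- pairs[order(pairs$u + pairs$d, pairs$u), , drop = FALSE]
  # gene ordinal per chromosome for intervening-gene counts
  ord <- stats::ave(seq_len(nrow(core_annotation)), core_annotation$chrom,
                    FUN = seq_along)
  for (r in seq_len(nrow(pairs))) {
    ug <- up[pairs$u[r]]; dg <- down[pairs$d[r]]
    if (!(ug %in% names(orthologs)) || !(dg %in% names(orthologs))) next
    iu <- locate(orthologs[[ug]]); id <- locate(orthologs[[dg]])
    if (is.null(iu) || is.null(id)) next
    if (core_annotation$chrom[iu] != core_annotation$chrom[id]) next
    if (abs(ord[iu] - ord[id]) - 1L > params$k) next
    a <- core_annotation[iu, ]; b <- core_annotation[id, ]
    return(gi(a$chrom, max(0L, min(a$start, b$start) - params$flank),
              max(a$end, b$end) + params$flank))
  }
  NULL
}

#' Collect the positional ortholog of a miRNA from one core species
#'
#' Extracts the shared syntenic region, searches it with the reference
#' pre-miRNA sequence, and confirms the best hit by a reverse search in
#' the reference genome. The confirmed hit is extended or trimmed
#' (centered) to the reference pre-miRNA length.
#'
#' @param mirna One-row miRNA table entry.
#' @param ref_annotation Reference gene annotation.
#' @param ref_genome Reference [genome_sequence()].
#' @param core A list with elements `genome` ([genome_sequence()]),
#'   `annotation` (gene annotation) and `orthologs` (named vector).
#' @param params [synteny_params()].
#' @param search_params [blast_params()].
#' @return The core pre-miRNA sequence (transcribed orientation), or
#'   `NULL` if no confirmed positional ortholog exists.
#' @export
collect_positional_ortholog <- function(mirna, ref_annotation, ref_genome,
                                        core, params = synteny_params(),
                                        search_params = blast_params()) {
  context <- classify_context(mirna, ref_annotation, params)
  region <- shared_syntenic_region(context, core$annotation, core$orthologs,
                                   params)
  if (is.null(region)) return(NULL)
  region$end <- min(region$end, core$genome$lengths[[region$chrom]])
  if (region$start >= region$end) return(NULL)
  region_seq <- extract_sequence(core$genome, region)
  mini <- genome_sequence(c(region = region_seq), assembly = "region")
  bh <- best_hit(local_search(mirna$sequence, mini, search_params))
  if (is.null(bh)) return(NULL)
  # extend/trim to the reference pre-miRNA length, centered on the hit
  L <- nchar(mirna$sequence)
  center <- (bh$start + bh$end) / 2
  s <- max(0L, as.integer(round(center - L / 2)))
  e <- s + L
  if (e > nchar(region_seq)) {
    e <- nchar(region_seq)
    s <- max(0L, e - L)
  }
  cand <- extract_sequence(mini, gi("region", s, e, bh$strand))
  if (!confirm_by_reverse_search(cand, ref_genome, mirna, search_params)) {
    return(NULL)
  }
  cand
}
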