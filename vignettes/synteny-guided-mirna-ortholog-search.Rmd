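---
title: "Synteny-guided search for miRNA orthologs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-guided search for miRNA orthologs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mirsynteny)
```

Annotating microRNAs across genome assemblies by plain sequence similarity
is unreliable in both directions: pre-miRNAs are short and partially
constrained only in the mature arm, so a best BLAST hit is often a
paralog, a repeat or nothing at all. `mirsynteny` implements a targeted,
two-stage alternative:

1. **Core-ortholog collection.** For each reference pre-miRNA, putative
   positional orthologs are collected from a small set of closely related
   *core* species using protein-coding genes as microsynteny anchors,
   and verified by a reciprocal best-hit criterion.
2. **Model search.** The reference hairpin and its core orthologs are
   aligned, the consensus secondary structure is folded, and a compact
   per-family sequence-plus-structure profile model (a covariance-model
   analogue) is trained. Target genomes are scanned with this model;
   hits reaching at least half of the reference's own score and
   confirmed by a reverse search against the reference genome are
   reported as (co-)orthologs.

This vignette documents the scoring mathematics, the synteny logic, the
search algorithm and the main design decisions, then walks through a
complete run on a simulated clade.

## Synteny context and core-ortholog collection

`classify_context()` places a reference miRNA relative to the gene
annotation: *intragenic* (contained in a host gene) or *intergenic*,
with the `n + 1` nearest upstream and downstream genes recorded as
alternative anchors (default `n = 1`). `shared_syntenic_region()` then
maps the context into a core species through the ortholog table:

* an intragenic miRNA maps to the ortholog of its host gene;
* an intergenic miRNA maps to the closest pair of anchor orthologs that
  lie on the same chromosome with at most `k` intervening genes between
  them (default `k = 3`), preferring the pair nearest to the miRNA
  (smallest combined anchor rank, ties broken upstream-first).

The resulting interval, extended by `flank` (default 100 nt), is
searched locally for the reference hairpin; the best hit passing
identity and coverage cutoffs, re-oriented to the transcribed strand, is
the core ortholog (`collect_positional_ortholog()`). Families without
syntenic support in any core species are trained from the reference
sequence alone, with a warning.

## The profile model

`build_training_alignment()` produces a star alignment anchored on the
(ungapped) reference row, and folds the consensus with a maximum
base-pairing dynamic program (Watson–Crick plus G:U wobble, minimum loop
3; an external folding engine can be substituted). `train_model()` then
fits, for `m` rows and column counts $c_i(a)$ (gapped rows excluded at
that column, Laplace pseudocount $\alpha = 1$):

$$e_i(a) = \log_2 \frac{(c_i(a)+\alpha)/(m+4\alpha)}{1/4}$$

and, for each paired column couple $(i, j)$ of the consensus structure,
a covariation term on top of the independent columns:

$$g_{ij}(a,b) = \log_2 \frac{(c_{ij}(a,b)+\alpha)/(m+16\alpha)}
{\hat p_i(a)\,\hat p_j(b)}$$

`score_sequence()` maximizes, over all monotone alignments of model
columns to sequence positions, the summed emissions minus a linear gap
penalty of 2 bits per unmatched column or position, plus the pair terms
evaluated on the optimal alignment. The tests verify this against full
enumeration of all column-to-position assignments for small models.

**Reference score calibration.** The score every candidate is compared
to, `s_ref`, is not the raw global score of the reference sequence:
`create_models()` re-derives it by running the *same* genomic scan over
the annotated reference locus and its flanks and keeping the best
overlapping hit (`calibrate_reference_score()`). Numerator and
denominator of a candidate's score fraction therefore come from one
scoring procedure, and a self-search of the reference genome returns
every locus at score fraction exactly 1. Models round-trip through a
plain-text `.cm` format (`write_cm()` / `read_cm()`) and export to
Stockholm alignments.

## Searching a target genome

`search_orthologs()` scans candidate windows with a free-end-gap variant
of the model alignment (all model columns must be accounted for;
flanking sequence is free), so a verbatim copy of the reference scores
exactly `s_ref`. Two modes share identical scoring:

* **quick** (default): windows are seeded by word matches of the
  reference sequence and extended by 1000 nt on each side;
* **exhaustive**: the whole genome is tiled with overlapping windows
  (overlap at least twice the model length), so any hit visible to the
  quick mode is also visible here — the quick mode's predictions are a
  subset by construction, which the acceptance tests verify.

Hits below `threshold * s_ref` (default 0.5) are discarded; overlapping
hits keep the best score; each survivor must be confirmed by a reverse
local search whose best hit in the reference genome overlaps the
original reference locus by at least one nucleotide. All confirmed hits
are kept as co-orthologs, ranked by score (`corank`).

## Downstream analyses

* `benchmark_predictions()` classifies every species-by-family cell
  against a gold standard (greedy, score-ranked interval matching; one
  overlapping nucleotide counts as a hit) and `metrics()` derives
  sensitivity, specificity, accuracy and F1, leaving undefined ratios as
  `NA` rather than 0. `naive_blast_call()` and `wga_block_call()` are
  the similarity-only and whole-genome-alignment baselines.
* `build_profiles()` turns predictions into gene- or family-level
  phylogenetic profiles; `date_family_origin()` dates a family to the
  most recent common ancestor of its carriers (including the reference);
  `co_ortholog_spectrum()` summarizes copy numbers, which exposes
  whole-genome duplications as a clade of species with two copies of
  most families; `build_supermatrix()` concatenates rank-1 orthologs,
  removing every alignment column whose gap fraction exceeds 0.5.
* `snp_density()`, `maf_fractions()` and `compare_densities()` contrast
  population variation between miRNA sub-regions (mature, star, loop,
  flanks) and other region classes.

## Simulated clades

`evolve_clade()` grows a genome clade along a seeded species tree:
protein-coding genes with intergenic spacers, planted hairpin miRNAs
(25-bp stem with G:U wobble, 12-nt loop), per-branch substitutions with
sub-region rate multipliers (mature ≤ star ≤ loop = flank), gene losses,
tandem duplications, gene-order inversions, and optional planted
whole-genome duplications and family gain nodes. Structural events are
suppressed on the root-to-reference lineage so the reference stays
single-copy. A truth table and gold standard make recovery exactly
measurable. The simulator is a generator of *favourable but non-trivial*
instances — it does not model repeats, assembly gaps or annotation
error, so simulated recovery rates are upper bounds on real-data
performance.

## Worked example

```{r pipeline}
sim <- evolve_clade(simulation_config(
  seed = 101, n_species = 6, n_genes = 80, n_mirnas = 6,
  p_sub = 0.02, p_loss = 0.1, n_core = 3))
res <- run_pipeline(sim)
unlist(res$metrics)
head(res$predictions[, c("species", "mirna_id", "chrom", "start", "end",
                         "strand", "score_fraction", "corank")])
```

Phylogenetic profiles and family dating from the predictions:

```{r profiles}
targets <- setdiff(sim$tree$tip.label, sim$ref_species)
pm <- build_profiles(res$predictions, sim$mirnas, targets)
fm <- collapse_to_family(pm)
fm$counts
date_family_origin(fm$counts[1, ], sim$tree, sim$ref_species)$label
```

The same workflow is available from the command line
(`inst/cli/mirsynteny.R`) with `simulate`, `create-models`, `search`,
`benchmark`, `profile`, `supermatrix` and `popvar` subcommands.

## Design decisions

Several behaviours are deliberate choices where reasonable alternatives
exist:

* **One-nucleotide overlap counts as recovery** in benchmarking: the
  search reports hit extents, not annotated precursor boundaries, and
  penalizing boundary disagreement would conflate two error types.
* **Seed identity is assessed on positions 2–8** of the mature arm after
  a global alignment of the prediction to the reference; if the mature
  annotation is missing, seed status is `NA`, never guessed.
* **Interval overlap ignores strand**: a hit on the opposite strand of a
  true locus almost always reflects a hairpin's reverse-complement
  symmetry rather than an independent locus.
* **The heuristic hit filter is score-preserving**: quick scans split
  windows recursively at score maxima; the filtered variant skips
  segments that provably (within a fixed slack) cannot reach the
  threshold, and the tests assert exact agreement with the unfiltered
  recursion.
* **Thresholds** — 50% of the calibrated reference score, `k = 3`
  intervening genes, `n = 1` alternative anchors, 100-nt flanks — are
  the package defaults and all exposed as parameters
  (`search_params()`, `synteny_params()`).
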