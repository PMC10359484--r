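# Shared fixtures, memoized so expensive simulations are built once per
# test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# a small clade: fast enough for module tests, rich enough to exercise the
# whole pipeline
small_sim <- function() {
  fixture("small_sim", function() {
    evolve_clade(simulation_config(
      seed = 101L, n_species = 6L, n_genes = 80L, n_mirnas = 6L,
      p_sub = 0.02, p_loss = 0.1, n_core = 3L))
  })
}

small_pipeline <- function() {
  fixture("small_pipeline", function() run_pipeline(small_sim()))
}

small_models <- function() {
  fixture("small_models", function() {
    sim <- small_sim()
    create_models(sim_reference_bundle(sim), sim_core_bundles(sim))
  })
}

# the full-scale clade of the end-to-end recovery test: 20 species,
# 3000 genes per genome, 50 miRNA families
big_sim <- function() {
  fixture("big_sim", function() {
    evolve_clade(simulation_config(
      seed = 7L, n_species = 20L, n_genes = 3000L, n_mirnas = 50L,
      p_sub = 0.01, p_loss = 0.05, n_core = 4L))
  })
}

# pipeline on the full-scale clade; wall time of the pipeline proper
# (training + search + benchmark) is recorded alongside the result
big_pipeline <- function() {
  fixture("big_pipeline", function() {
    sim <- big_sim()
    t0 <- proc.time()[["elapsed"]]
    res <- run_pipeline(sim)
    res$elapsed_s <- proc.time()[["elapsed"]] - t0
    res
  })
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-mutate a fraction of positions (never into the original base)
mutate_dna_str <- function(s, frac) {
  chars <- strsplit(s, "")[[1]]
  k <- max(0L, round(frac * length(chars)))
  if (k > 0) {
    pos <- sample(seq_along(chars), k)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# hand-rolled annotation constructor
make_annotation <- function(gene_id, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}
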