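# The clade simulator: hairpin generation, determinism, the evolutionary
# event model (losses, duplications, whole-genome duplication, gene-order
# inversions) and the bundle writer.

quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_species = 4L, n_genes = 40L, n_mirnas = 4L, n_core = 2L)
  defaults <- defaults[!names(defaults) %in% names(args)]
  do.call(simulation_config, c(args, defaults))
}

test_that("configuration validation enforces the documented constraints", {
  expect_error(simulation_config(p_sub = 1.5), "p_sub")
  expect_error(simulation_config(p_loss = -0.1), "p_loss")
  expect_error(simulation_config(mult_mature = 0.9, mult_star = 0.5),
               "mult_mature <= mult_star")
  expect_error(simulation_config(stem = 20L, loop_len = 5L), "55-70")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("generated hairpins have complementary stems and canonical sub-regions", {
  set.seed(89)
  # without wobble the 3' arm is the exact reverse complement of the 5' arm
  hp0 <- generate_hairpin(stem = 25L, loop_len = 12L, wobble = 0)
  expect_equal(nchar(hp0$seq), 62L)
  expect_equal(substr(hp0$seq, 38, 62),
               reverse_complement(substr(hp0$seq, 1, 25)))
  expect_equal(hp0$mature, c(1L, 22L))
  expect_equal(hp0$loop, c(26L, 37L))
  expect_equal(hp0$star, c(41L, 62L))
  # with wobble every stem position still pairs (Watson-Crick or G:T)
  for (rep in 1:10) {
    hp <- generate_hairpin(stem = 25L, loop_len = 12L, wobble = 0.3)
    a5 <- strsplit(substr(hp$seq, 1, 25), "")[[1]]
    a3 <- rev(strsplit(substr(hp$seq, 38, 62), "")[[1]])
    ok <- paste0(a5, a3) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
    expect_true(all(ok))
  }
  expect_error(generate_hairpin(stem = 10L), "mature arm")
})

test_that("the simulation is a deterministic function of its configuration", {
  s1 <- evolve_clade(quick_cfg(seed = 400L))
  s2 <- evolve_clade(quick_cfg(seed = 400L))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$mirnas, s2$mirnas)
  expect_identical(s1$species[["s03"]]$genome$seqs,
                   s2$species[["s03"]]$genome$seqs)
  s3 <- evolve_clade(quick_cfg(seed = 401L))
  expect_false(identical(s1$species[["s03"]]$genome$seqs,
                         s3$species[["s03"]]$genome$seqs))
})

test_that("the reference species carries every family exactly once at the annotated locus", {
  sim <- small_sim()
  ref <- sim$truth[sim$truth$species == sim$ref_species, ]
  expect_true(all(ref$present))
  expect_equal(sort(ref$mirna_id), sort(sim$mirnas$mirna_id))
  expect_true(all(table(ref$mirna_id) == 1L))
  # annotated sequence matches the reference genome at the stated interval
  g <- sim$species[[sim$ref_species]]$genome
  for (r in seq_len(nrow(sim$mirnas))) {
    m <- sim$mirnas[r, ]
    expect_equal(extract_sequence(g, gi(m$chrom, m$start, m$end, m$strand)),
                 m$sequence)
  }
  # gold rows are exactly the present truth rows
  tp <- sim$truth[sim$truth$present, c("species", "family_id", "chrom",
                                       "start", "end", "strand")]
  gp <- sim$gold[, c("species", "family_id", "chrom", "start", "end",
                     "strand")]
  rownames(tp) <- NULL; rownames(gp) <- NULL
  expect_equal(tp[order(tp$species, tp$family_id, tp$start), ],
               gp[order(gp$species, gp$family_id, gp$start), ])
})

test_that("with all event probabilities zero every species keeps one identical-seed copy", {
  sim <- evolve_clade(quick_cfg(seed = 402L, p_sub = 0, p_loss = 0,
                                p_dup = 0, inversions_per_branch = 0))
  expect_true(all(sim$truth$present))
  expect_true(all(sim$truth$copy == 1L))
  expect_true(all(sim$truth$seed_identical))
  # gene order is fully conserved without inversions
  ref_order <- sim$species[[sim$ref_species]]$annotation$gene_id
  for (sp in names(sim$species)) {
    expect_equal(sim$species[[sp]]$annotation$gene_id, ref_order)
  }
})

test_that("losses remove copies off the reference lineage and are recorded", {
  sim <- evolve_clade(quick_cfg(seed = 403L, n_species = 6L, p_loss = 0.5,
                                p_dup = 0))
  absent <- sim$truth[!sim$truth$present, ]
  expect_gt(nrow(absent), 0L)
  expect_false(sim$ref_species %in% absent$species)
  # every absent copy of a family is explained by a recorded loss node
  expect_true(all(nzchar(absent$loss_nodes)))
})

test_that("a whole-genome duplication doubles miRNA copies below its node only", {
  base <- evolve_clade(quick_cfg(seed = 404L, n_species = 6L, p_loss = 0,
                                 p_dup = 0))
  # pick a clade disjoint from the reference lineage
  tree <- base$tree
  wgd_node <- ape::getMRCA(tree, c("s05", "s06"))
  wgd_label <- tree$node.label[wgd_node - ape::Ntip(tree)]
  wgd_tips <- node_tips(tree, wgd_node)
  expect_false(base$ref_species %in% wgd_tips)
  sim <- evolve_clade(quick_cfg(seed = 404L, n_species = 6L, p_loss = 0,
                                p_dup = 0, wgd_nodes = wgd_label))
  copies <- stats::aggregate(copy ~ species + mirna_id,
                             data = sim$truth[sim$truth$present, ], FUN = max)
  inside <- copies$species %in% wgd_tips
  expect_true(all(copies$copy[inside] == 2L))
  expect_true(all(copies$copy[!inside] == 1L))
  # duplicated chromosomes and gene copies carry the duplication suffix
  sp <- wgd_tips[1]
  expect_true(any(grepl("w$", names(sim$species[[sp]]$genome$seqs))))
  expect_error(evolve_clade(quick_cfg(wgd_nodes = "nope")), "unknown WGD")
})

test_that("family gains restrict presence to the gained subtree", {
  base <- evolve_clade(quick_cfg(seed = 405L, n_species = 6L, p_loss = 0,
                                 p_dup = 0))
  tree <- base$tree
  # the reference's immediate ancestor: a proper subtree containing s01
  ref_tip <- which(tree$tip.label == base$ref_species)
  anc <- phangorn::Ancestors(tree, ref_tip, type = "parent")
  gain_label <- tree$node.label[anc - ape::Ntip(tree)]
  gain_tips <- node_tips(tree, anc)
  expect_lt(length(gain_tips), 6L)
  sim <- evolve_clade(quick_cfg(
    seed = 405L, n_species = 6L, p_loss = 0, p_dup = 0,
    gain_nodes = c(mir002 = gain_label)))
  t2 <- sim$truth[sim$truth$mirna_id == "mir002", ]
  expect_setequal(t2$species[t2$present], gain_tips)
  expect_true(all(!t2$present[!t2$species %in% gain_tips]))
  expect_true(all(t2$gain_node == gain_label))
  # other families remain clade-wide
  t1 <- sim$truth[sim$truth$mirna_id == "mir001", ]
  expect_true(all(t1$present))
  # gain nodes must lie on the root-to-reference lineage
  off_label <- tree$node.label[ape::getMRCA(tree, c("s05", "s06")) -
                                 ape::Ntip(tree)]
  expect_error(evolve_clade(quick_cfg(gain_nodes = c(mir001 = off_label),
                                      n_species = 6L)),
               "root-to-reference")
})

test_that("inversions shuffle gene order but preserve gene content", {
  sim <- evolve_clade(quick_cfg(seed = 406L, n_species = 4L, p_loss = 0,
                                p_dup = 0, inversions_per_branch = 4))
  ref_genes <- sim$species[[sim$ref_species]]$annotation$gene_id
  changed <- FALSE
  for (sp in setdiff(names(sim$species), sim$ref_species)) {
    genes <- sim$species[[sp]]$annotation$gene_id
    expect_setequal(genes, ref_genes)
    if (!identical(genes, ref_genes)) changed <- TRUE
  }
  expect_true(changed)
})

test_that("clade bundles round-trip through the standard on-disk formats", {
  sim <- small_sim()
  dir <- tempfile("bundle")
  write_clade_bundle(sim, dir)
  for (sp in names(sim$species)) {
    g <- read_genome_fasta(file.path(dir, paste0(sp, ".fa")), assembly = sp)
    expect_equal(g$seqs, sim$species[[sp]]$genome$seqs)
    ann <- read_gene_annotation(file.path(dir, paste0(sp, ".gff3")))
    expect_equal(ann, sim$species[[sp]]$annotation)
    orth <- read_ortholog_table(file.path(dir, paste0(sp, ".orthologs.tsv")))
    expect_equal(orth, sim$species[[sp]]$orthologs)
  }
  mir <- read_mirna_table(file.path(dir, "reference_mirnas.tsv"))
  expect_equal(mir$sequence, sim$mirnas$sequence)
  gold <- read_gold_standard(file.path(dir, "gold.tsv"))
  expect_equal(nrow(gold), nrow(sim$gold))
  tree <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  expect_setequal(tree$tip.label, names(sim$species))
})
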