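# Profile model training: the log-odds emission and covariation formulas
# are checked against hand-computed closed forms, the folder against an
# exhaustive structure enumeration, and the scorer against an exhaustive
# alignment enumeration.

# a training_alignment built by hand, bypassing the aligner
manual_alignment <- function(msa_rows, pairs = NULL) {
  msa <- do.call(rbind, lapply(msa_rows, function(s) strsplit(s, "")[[1]]))
  rownames(msa) <- paste0("s", seq_along(msa_rows))
  if (is.null(pairs)) {
    pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  } else {
    pairs <- matrix(pairs, ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("i", "j")))
  }
  structure(list(msa = msa, pairs = pairs,
                 consensus = paste(msa[1, ], collapse = ""),
                 ref_name = "s1"),
            class = "training_alignment")
}

test_that("single-column emissions equal the hand-computed log-odds closed forms", {
  # one training sequence: e(observed) = log2((1+1)/(1+4)/0.25) = log2(1.6)
  m1 <- train_model(manual_alignment("ACGT"), mirna_id = "t1")
  expect_equal(unname(m1$emis["A", 1]), log2(1.6), tolerance = 1e-12)
  expect_equal(unname(m1$emis["C", 2]), log2(1.6), tolerance = 1e-12)
  expect_equal(unname(m1$emis["C", 1]), log2(0.8), tolerance = 1e-12)  # unobserved
  # four identical sequences: e(A) = log2((4+1)/(4+4)/0.25) = log2(2.5)
  m4 <- train_model(manual_alignment(rep("AAAAA", 4)), mirna_id = "t4")
  expect_equal(unname(m4$emis["A", ]), rep(log2(2.5), 5), tolerance = 1e-12)
  expect_equal(unname(m4$emis["G", ]), rep(log2(0.5), 5), tolerance = 1e-12)
  # a gapped row contributes to no base count but stays in the denominator
  mg <- train_model(manual_alignment(c("A", "-")), mirna_id = "tg")
  expect_equal(unname(mg$emis["A", 1]), log2((1 + 1) / (2 + 4) / 0.25),
               tolerance = 1e-12)
})

test_that("pairwise covariation terms equal the hand-computed closed forms", {
  # five sequences, all A...T at a conserved pair (columns 1 and 5):
  # g(A,T) = log2( (5+1)/(5+16) / ((6/9)*(6/9)) ) = log2(9/14)
  aln <- manual_alignment(rep("ACGCT", 5), pairs = c(1L, 5L))
  m <- train_model(aln, mirna_id = "tp")
  g <- m$pair_emis[[1]]
  expect_equal(unname(g["A", "T"]), log2(9 / 14), tolerance = 1e-12)
  # unobserved combination of unobserved bases:
  # log2( (0+1)/21 / ((1/9)*(1/9)) ) = log2(81/21)
  expect_equal(unname(g["C", "G"]), log2(81 / 21), tolerance = 1e-12)
  # the reference score includes the pair bonus
  expect_equal(m$s_ref,
               5 * log2(8 / 3) + log2(9 / 14),
               tolerance = 1e-12)
})

test_that("the builtin folder attains the exhaustively enumerated maximum pair count", {
  set.seed(5)
  seqs <- c("GGGAAACCC", "ACGTACGT", "GTTTAAAC", "AAAAAAAA",
            replicate(25, random_dna_str(sample(6:11, 1))))
  for (s in seqs) {
    partner <- fold_sequence(s, min_loop = 3L)
    got_pairs <- sum(!is.na(partner)) / 2
    expect_equal(got_pairs, oracle_max_pairs(s, 3L), info = s)
    # returned structure is a valid nesting of complementary pairs
    for (i in seq_along(partner)) {
      j <- partner[i]
      if (!is.na(j)) {
        expect_equal(partner[j], i)
        if (j > i) expect_gte(j - i, 4L)  # min_loop = 3 unpaired between
      }
    }
  }
})

test_that("model scoring equals an exhaustive enumeration of all alignments", {
  set.seed(17)
  for (rep in 1:60) {
    L <- sample(2:8, 1)
    model <- random_profile_model(L)
    n <- sample(1:9, 1)
    seq <- random_dna_str(n)
    expect_equal(score_sequence(model, seq),
                 oracle_model_score(model, encode_dna(seq)),
                 tolerance = 1e-9, info = sprintf("rep %d L=%d n=%d", rep, L, n))
  }
})

test_that("training alignments fold the consensus and project pairs onto columns", {
  # a clean hairpin: 6-pair stem, 4-nt loop
  stem <- "GGCGGC"
  hp <- paste0(stem, "TTTT", reverse_complement(stem))
  expect_warning(aln <- build_training_alignment(c(ref = hp)),
                 "single training sequence")
  expect_equal(ncol(aln$msa), nchar(hp))
  expect_equal(nrow(aln$pairs), 6L)
  expect_equal(aln$pairs[, "i"] + aln$pairs[, "j"], rep(nchar(hp) + 1L, 6))
  # with diverged copies, the reference row stays ungapped and first
  copies <- c(ref = hp, a = mutate_dna_str(hp, 0.1), b = mutate_dna_str(hp, 0.1))
  aln2 <- build_training_alignment(copies)
  expect_equal(rownames(aln2$msa)[1], "ref")
  expect_equal(paste(aln2$msa[1, aln2$msa[1, ] != "-"], collapse = ""), hp)
})

test_that("models survive a plain-text round trip bit-exactly", {
  set.seed(23)
  hp <- paste0("GGCGGCAGC", "TTTT", reverse_complement("GGCGGCAGC"))
  seqs <- c(mir = hp, a = mutate_dna_str(hp, 0.08), b = mutate_dna_str(hp, 0.12))
  model <- train_model(build_training_alignment(seqs), mirna_id = "mir")
  path <- tempfile(fileext = ".cm")
  write_cm(model, path)
  back <- read_cm(path)
  expect_identical(back$mirna_id, model$mirna_id)
  expect_equal(back$emis, model$emis, tolerance = 0)
  expect_equal(back$pair_emis, model$pair_emis, tolerance = 0)
  expect_equal(unname(back$pairs), unname(model$pairs))
  expect_equal(back$s_ref, model$s_ref, tolerance = 0)
  expect_equal(back$gap, model$gap)
  expect_equal(back$nseq, model$nseq)
  # the restored model scores sequences identically
  probe <- mutate_dna_str(hp, 0.2)
  expect_identical(score_sequence(back, probe), score_sequence(model, probe))
})

test_that("the reference sequence scores fraction one of the model maximum", {
  set.seed(29)
  hp <- paste0("GCAGCGGCA", "AGCT", reverse_complement("GCAGCGGCA"))
  seqs <- c(mir = hp, a = mutate_dna_str(hp, 0.1))
  model <- train_model(build_training_alignment(seqs), mirna_id = "mir")
  expect_equal(predict(model, hp, type = "fraction"), 1.0, tolerance = 1e-12)
  expect_equal(predict(model, hp, type = "bits"), model$s_ref)
  # diverged probes score strictly lower
  expect_lt(predict(model, mutate_dna_str(hp, 0.3), type = "fraction"), 1.0)
  expect_equal(coef(model), model$emis)
})

test_that("Stockholm output carries the alignment and consensus structure", {
  hp <- paste0("GGCGGC", "TTTT", reverse_complement("GGCGGC"))
  aln <- suppressWarnings(build_training_alignment(c(mirX = hp)))
  path <- tempfile(fileext = ".sto")
  write_stockholm(aln, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# STOCKHOLM 1.0")
  expect_equal(lines[length(lines)], "//")
  expect_true(any(grepl("^mirX ", lines)))
  ss <- lines[grepl("#=GC SS_cons", lines)]
  db <- sub(".*SS_cons\\s+", "", ss)
  expect_equal(sum(strsplit(db, "")[[1]] == "("), 6L)
  expect_equal(sum(strsplit(db, "")[[1]] == ")"), 6L)
})

test_that("the external RNAfold adapter returns a valid structure for a perfect hairpin", {
  stem <- "GGCGCGGCC"
  hp <- paste0(stem, "AAAA", reverse_complement(stem))
  partner <- fold_sequence(hp, engine = "rnafold")
  expect_length(partner, nchar(hp))
  expect_gte(sum(!is.na(partner)) / 2, 7)   # near-full stem recovered
  for (i in seq_along(partner)) {
    if (!is.na(partner[i])) expect_equal(partner[partner[i]], i)
  }
})

test_that("model construction from bundles reports core-ortholog support", {
  res <- small_models()
  sim <- small_sim()
  expect_setequal(names(res$models), sim$mirnas$mirna_id)
  expect_true(all(res$report$n_core_orthologs >= 0))
  expect_true(all(res$report$n_core_orthologs <= length(sim$core_species)))
  for (m in res$models) {
    expect_s3_class(m, "mirna_cm")
    expect_gt(m$s_ref, 0)
    expect_equal(m$nseq, res$report$n_core_orthologs[
      res$report$mirna_id == m$mirna_id] + 1L)
  }
})
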