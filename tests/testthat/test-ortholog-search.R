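# Targeted ortholog search: candidate-region construction, region
# scanning (checked with planted loci whose optimal score is known
# exactly) and the acceptance / co-ortholog logic.

# a trained hairpin model plus its reference row, used across tests
planted_model <- function(seed = 31) {
  set.seed(seed)
  stem <- random_dna_str(25)
  hp <- paste0(stem, random_dna_str(12), reverse_complement(stem))
  seqs <- c(mir = hp, a = mutate_dna_str(hp, 0.06), b = mutate_dna_str(hp, 0.1))
  list(model = train_model(build_training_alignment(seqs), mirna_id = "mir"),
       hp = hp)
}

test_that("quick candidate regions extend similarity hits and clip at chromosome ends", {
  set.seed(37)
  pre <- random_dna_str(62)
  chrom_seq <- paste0(random_dna_str(150), pre, random_dna_str(5000))
  g <- genome_sequence(c(chr1 = chrom_seq))
  mirna <- data.frame(mirna_id = "m", sequence = pre, stringsAsFactors = FALSE)
  regions <- candidate_regions(mirna, g, search_params(mode = "quick",
                                                       extension = 1000L))
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$start, 0L)             # 150 - 1000, clipped at 0
  expect_equal(regions$end, 212L + 1000L)     # hit end + extension
  # no similarity hit: no candidate regions
  g2 <- genome_sequence(c(chr1 = strrep("A", 3000)))
  expect_equal(nrow(candidate_regions(
    data.frame(sequence = strrep("CG", 31)), g2,
    search_params(mode = "quick"))), 0L)
})

test_that("exhaustive tiling covers every chromosome with overlapping windows", {
  g <- genome_sequence(c(c1 = strrep("ACGT", 2000), c2 = strrep("ACGT", 100)))
  params <- search_params(mode = "exhaustive", extension = 500L)
  regions <- candidate_regions(NULL, g, params, model_length = 62L)
  # every position of every chromosome lies in some window
  for (ch in c("c1", "c2")) {
    r <- regions[regions$chrom == ch, ]
    expect_equal(min(r$start), 0L)
    expect_equal(max(r$end), unname(g$lengths[[ch]]))
    r <- r[order(r$start), ]
    if (nrow(r) > 1) {
      # consecutive windows overlap by at least twice the model length,
      # so no locus of model length can straddle a window boundary unseen;
      # a window already clipped at the chromosome end cannot miss anything
      len <- unname(g$lengths[[ch]])
      ov <- r$end[-nrow(r)] - r$start[-1]
      expect_true(all(ov >= 2L * 62L | r$end[-nrow(r)] == len))
    }
  }
})

test_that("a verbatim copy of the reference locus recovers exactly the reference score", {
  pm <- planted_model()
  set.seed(41)
  g <- genome_sequence(c(chr1 = paste0(random_dna_str(500), pm$hp,
                                       random_dna_str(500))))
  hit <- scan_region(pm$model, g, gi("chr1", 0L, unname(g$lengths[["chr1"]])))
  expect_equal(hit$score, pm$model$s_ref, tolerance = 1e-9)
  expect_equal(hit$start, 500L)
  expect_equal(hit$end, 500L + nchar(pm$hp))
  expect_equal(hit$strand, "+")
  # the same locus planted in reverse complement is found on the minus strand
  g2 <- genome_sequence(c(chr1 = paste0(random_dna_str(500),
                                        reverse_complement(pm$hp),
                                        random_dna_str(500))))
  hit2 <- scan_region(pm$model, g2, gi("chr1", 0L, unname(g2$lengths[["chr1"]])))
  expect_equal(hit2$score, pm$model$s_ref, tolerance = 1e-9)
  expect_equal(hit2$start, 500L)
  expect_equal(hit2$end, 500L + nchar(pm$hp))
  expect_equal(hit2$strand, "-")
})

test_that("the heuristic diagonal prefilter agrees with the direct recursive scan", {
  pm <- planted_model(43)
  set.seed(47)
  copies <- c(pm$hp, mutate_dna_str(pm$hp, 0.05), mutate_dna_str(pm$hp, 0.12))
  seq <- paste0(random_dna_str(800), copies[1], random_dna_str(900),
                copies[2], random_dna_str(700), copies[3],
                random_dna_str(800))
  enc <- encode_dna(seq)
  min_keep <- 0.5 * pm$model$s_ref
  direct <- scan_hits_recursive(pm$model, enc, min_keep)
  filtered <- scan_hits_filtered(pm$model, enc, min_keep)
  direct <- direct[order(direct$start), ]
  filtered <- filtered[order(filtered$start), ]
  expect_equal(nrow(filtered), 3L)
  expect_equal(filtered$start, direct$start)
  expect_equal(filtered$end, direct$end)
  expect_equal(filtered$score, direct$score, tolerance = 1e-9)
})

test_that("orthologs are accepted above the score threshold and rejected below it", {
  pm <- planted_model(53)
  set.seed(59)
  ref_genome <- genome_sequence(c(chr1 = paste0(random_dna_str(300), pm$hp,
                                                random_dna_str(300))))
  mirna <- data.frame(
    mirna_id = "mir", family_id = "fam", chrom = "chr1", start = 300L,
    end = 300L + nchar(pm$hp), strand = "+", sequence = pm$hp,
    mature_start = 300L, mature_end = 322L, stringsAsFactors = FALSE)
  # target carries a mildly diverged copy: accepted
  good <- mutate_dna_str(pm$hp, 0.05)
  tg <- genome_sequence(c(tc1 = paste0(random_dna_str(400), good,
                                       random_dna_str(400))))
  preds <- search_orthologs(pm$model, mirna, tg, ref_genome)
  expect_equal(nrow(preds), 1L)
  expect_equal(preds$chrom, "tc1")
  expect_gte(preds$score_fraction, 0.5)
  expect_equal(preds$corank, 1L)
  expect_true(abs(preds$start - 400L) <= 3)
  # heavily diverged copy: below threshold, absent from predictions
  bad <- mutate_dna_str(pm$hp, 0.45)
  tg2 <- genome_sequence(c(tc1 = paste0(random_dna_str(400), bad,
                                        random_dna_str(400))))
  expect_equal(nrow(search_orthologs(pm$model, mirna, tg2, ref_genome)), 0L)
  # raising the threshold to 1 rejects the mildly diverged copy too
  expect_equal(nrow(search_orthologs(
    pm$model, mirna, tg, ref_genome,
    search_params(threshold = 1))), 0L)
})

test_that("co-orthologs are all reported and ranked by score", {
  pm <- planted_model(61)
  set.seed(67)
  ref_genome <- genome_sequence(c(chr1 = paste0(random_dna_str(300), pm$hp,
                                                random_dna_str(300))))
  mirna <- data.frame(
    mirna_id = "mir", family_id = "fam", chrom = "chr1", start = 300L,
    end = 300L + nchar(pm$hp), strand = "+", sequence = pm$hp,
    mature_start = 300L, mature_end = 322L, stringsAsFactors = FALSE)
  close_copy <- mutate_dna_str(pm$hp, 0.03)
  far_copy <- mutate_dna_str(pm$hp, 0.10)
  tg <- genome_sequence(c(tc1 = paste0(random_dna_str(400), far_copy,
                                       random_dna_str(1500), close_copy,
                                       random_dna_str(400))))
  preds <- search_orthologs(pm$model, mirna, tg, ref_genome)
  expect_equal(nrow(preds), 2L)
  expect_equal(preds$corank, c(1L, 2L))
  expect_true(all(diff(preds$bit_score) <= 0))   # rank 1 scores highest
  expect_gt(preds$start[1], preds$start[2])      # closer copy planted second
})

test_that("quick and exhaustive modes find the same planted orthologs", {
  pm <- planted_model(71)
  set.seed(73)
  ref_genome <- genome_sequence(c(chr1 = paste0(random_dna_str(300), pm$hp,
                                                random_dna_str(300))))
  mirna <- data.frame(
    mirna_id = "mir", family_id = "fam", chrom = "chr1", start = 300L,
    end = 300L + nchar(pm$hp), strand = "+", sequence = pm$hp,
    mature_start = 300L, mature_end = 322L, stringsAsFactors = FALSE)
  copy <- mutate_dna_str(pm$hp, 0.06)
  tg <- genome_sequence(c(tc1 = paste0(random_dna_str(2500),
                                       reverse_complement(copy),
                                       random_dna_str(2500))))
  quick <- search_orthologs(pm$model, mirna, tg, ref_genome,
                            search_params(mode = "quick"))
  exh <- search_orthologs(pm$model, mirna, tg, ref_genome,
                          search_params(mode = "exhaustive"))
  expect_equal(nrow(quick), 1L)
  expect_equal(quick$start, exh$start)
  expect_equal(quick$end, exh$end)
  expect_equal(quick$strand, "-")
  expect_equal(quick$bit_score, exh$bit_score, tolerance = 1e-9)
})

test_that("seed identity compares the seven aligned mature seed nucleotides", {
  hp <- paste0(strrep("GCAT", 6), "TTTTTTTTTTTTTT",
               reverse_complement(strrep("GCAT", 6)))
  mirna <- data.frame(
    mirna_id = "m", chrom = "chr1", start = 1000L, end = 1000L + nchar(hp),
    strand = "+", sequence = hp, mature_start = 1000L, mature_end = 1022L,
    stringsAsFactors = FALSE)
  expect_true(seed_identical(mirna, hp))
  # a substitution inside seed positions 2-8 of the mature arm
  seedless <- hp
  substr(seedless, 4, 4) <- if (substr(hp, 4, 4) == "A") "C" else "A"
  expect_false(seed_identical(mirna, seedless))
  # a substitution outside the seed leaves identity intact
  tail_mut <- hp
  substr(tail_mut, nchar(hp) - 1, nchar(hp) - 1) <-
    if (substr(hp, nchar(hp) - 1, nchar(hp) - 1) == "A") "C" else "A"
  expect_true(seed_identical(mirna, tail_mut))
  # minus-strand miRNA: the offset counts from the transcript 5' end
  mirna_minus <- mirna
  mirna_minus$strand <- "-"
  mirna_minus$mature_start <- mirna$end - 22L
  mirna_minus$mature_end <- mirna$end
  expect_true(seed_identical(mirna_minus, hp))
  # no mature annotation: unknown
  mirna_na <- mirna
  mirna_na$mature_start <- NA_integer_
  expect_true(is.na(seed_identical(mirna_na, hp)))
})
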