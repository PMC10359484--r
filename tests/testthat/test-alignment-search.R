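# The built-in seed-and-extend local search engine, checked against
# independent oracles (naive R scans and Biostrings dynamic programming)
# and against the external blastn adapter.

test_that("exact-word seeding agrees with a naive R scan", {
  set.seed(42)
  for (rep in 1:25) {
    w <- sample(4:12, 1)
    q <- random_dna_str(sample(20:40, 1))
    s <- paste0(random_dna_str(100), substr(q, 3, 3 + w + 4), random_dna_str(100))
    qi <- encode_dna(q); si <- encode_dna(s)
    got <- sort(seed_hits_cpp(qi, si, w))
    # oracle: every w-mer of q, located by fixed-string matching in s
    words <- unique(vapply(seq_len(nchar(q) - w + 1),
                           function(i) substr(q, i, i + w - 1), character(1)))
    want <- sort(unique(unlist(lapply(words, function(wd) {
      hits <- gregexpr(wd, s, fixed = TRUE)[[1]]
      # gregexpr skips overlapping occurrences; rescan manually
      found <- integer(0)
      for (p in seq_len(nchar(s) - w + 1)) {
        if (substr(s, p, p + w - 1) == wd) found <- c(found, p - 1L)
      }
      found
    }))))
    expect_equal(got, want, info = sprintf("rep %d w=%d", rep, w))
  }
})

test_that("seeding skips words containing ambiguous bases", {
  qi <- encode_dna("ACGTNACGT")
  si <- encode_dna("ACGTACGTNACGTA")
  # only unambiguous 4-mers of the query can seed; positions containing the
  # subject N must never be reported
  hits <- seed_hits_cpp(qi, si, 4L)
  for (h in hits) {
    expect_false(grepl("N", substr("ACGTACGTNACGTA", h + 1, h + 4)))
  }
  expect_true(0L %in% hits)  # ACGT at subject position 0
})

test_that("global alignment matches the Biostrings dynamic-programming oracle", {
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (rep in 1:40) {
    a <- random_dna_str(sample(5:40, 1))
    b <- mutate_dna_str(random_dna_str(sample(5:40, 1)), 0)
    al <- global_align(a, b)
    oracle <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    expect_equal(al$score, Biostrings::score(oracle))
    # the returned gapped strings must be a valid alignment of a and b
    expect_equal(gsub("-", "", al$a), a)
    expect_equal(gsub("-", "", al$b), b)
    expect_equal(nchar(al$a), nchar(al$b))
  }
})

test_that("local extension reproduces Smith-Waterman scores from an independent aligner", {
  set.seed(11)
  p <- blast_params(word_size = 5L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = p$match,
                                                  mismatch = p$mismatch)
  for (rep in 1:60) {
    q <- random_dna_str(sample(25:60, 1))
    s <- mutate_dna_str(q, 0.15)  # diverged copy, guaranteed seedable
    al <- sw_align_cpp(encode_dna(q), encode_dna(s), p$match, p$mismatch,
                       p$gap_open, p$gap_extend)
    oracle <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = mat,
      gapOpening = p$gap_open, gapExtension = p$gap_extend)
    expect_equal(al$score, Biostrings::score(oracle), info = paste("rep", rep))
  }
})

test_that("a planted locus is recovered with exact coordinates on both strands", {
  set.seed(3)
  q <- random_dna_str(62)
  left <- random_dna_str(300)
  right <- random_dna_str(300)
  g <- genome_sequence(c(
    chrP = paste0(left, q, right),
    chrM = paste0(right, reverse_complement(q), left)))
  hits <- local_search(q, g)
  hp <- hits[hits$chrom == "chrP", ][1, ]
  hm <- hits[hits$chrom == "chrM", ][1, ]
  expect_equal(hp$start, 300L)
  expect_equal(hp$end, 362L)
  expect_equal(hp$strand, "+")
  expect_equal(hp$identity, 100)
  expect_equal(hp$coverage, 100)
  expect_equal(hp$subject_seq, q)       # reported in query orientation
  expect_equal(hm$start, 300L)
  expect_equal(hm$end, 362L)
  expect_equal(hm$strand, "-")
  expect_equal(hm$subject_seq, q)
  # bit score of the perfect hit follows the stated conversion formula
  p <- blast_params()
  raw <- p$match * 62
  expect_equal(hp$bit_score, (p$lambda * raw - log(p$K)) / log(2))
})

test_that("searches with no seed matches return a typed empty hit table", {
  g <- genome_sequence(c(chr1 = strrep("A", 200)))
  hits <- local_search(strrep("CG", 20), g)
  expect_equal(nrow(hits), 0L)
  expect_true(all(c("chrom", "start", "end", "strand", "bit_score",
                    "identity", "coverage", "subject_seq") %in% names(hits)))
  expect_null(best_hit(hits))
  expect_error(local_search("ACGT", g), "word size")
})

test_that("overlapping hits are deduplicated keeping the best-scoring one", {
  mk <- function(start, end, bits, strand = "+", chrom = "c1") {
    data.frame(query_id = "q", chrom = chrom, start = start, end = end,
               strand = strand, bit_score = bits, identity = 100,
               coverage = 100, subject_seq = "A", stringsAsFactors = FALSE)
  }
  out <- finalize_hits(list(mk(100, 160, 50), mk(120, 180, 80),
                            mk(160, 220, 40),     # touches hit 1, overlaps hit 2
                            mk(500, 560, 30),     # disjoint, survives
                            mk(100, 160, 60, chrom = "c2")))  # other chromosome
  expect_equal(nrow(out), 3L)
  expect_equal(out$bit_score, c(80, 60, 30))
  expect_equal(out$start, c(120L, 100L, 500L))
})

test_that("reverse-search confirmation accepts the source locus and rejects foreign sequence", {
  set.seed(8)
  pre <- random_dna_str(62)
  ref <- genome_sequence(c(chr1 = paste0(random_dna_str(200), pre,
                                         random_dna_str(200))))
  mirna <- data.frame(mirna_id = "m", chrom = "chr1", start = 200L,
                      end = 262L, strand = "+", stringsAsFactors = FALSE)
  expect_true(confirm_by_reverse_search(pre, ref, mirna))
  expect_true(confirm_by_reverse_search(mutate_dna_str(pre, 0.1), ref, mirna))
  # a candidate whose best reference hit lies elsewhere is rejected
  decoy <- random_dna_str(62)
  ref2 <- genome_sequence(c(chr1 = paste0(decoy, random_dna_str(150), pre,
                                          random_dna_str(150))))
  mirna2 <- mirna; mirna2$start <- 212L; mirna2$end <- 274L
  expect_false(confirm_by_reverse_search(decoy, ref2, mirna2))
})

test_that("annotation liftover enforces identity and coverage cutoffs", {
  set.seed(13)
  pre <- random_dna_str(62)
  mirna <- data.frame(mirna_id = "m", sequence = pre,
                      stringsAsFactors = FALSE)
  close_copy <- mutate_dna_str(pre, 0.05)   # ~95% identity
  far_copy <- mutate_dna_str(pre, 0.25)     # well below 90% identity
  g <- genome_sequence(c(chrA = paste0(random_dna_str(100), close_copy,
                                       random_dna_str(100))))
  iv <- liftover_mirna(mirna, g)
  expect_false(is.null(iv))
  expect_equal(iv$chrom, "chrA")
  expect_true(iv$start >= 90 && iv$end <= 172)
  g2 <- genome_sequence(c(chrA = paste0(random_dna_str(100), far_copy,
                                        random_dna_str(100))))
  expect_null(liftover_mirna(mirna, g2))
  # a perfect but truncated copy fails the coverage cutoff
  g3 <- genome_sequence(c(chrA = paste0(random_dna_str(100),
                                        substr(pre, 1, 40),
                                        random_dna_str(100))))
  expect_null(liftover_mirna(mirna, g3))
  expect_error(liftover_mirna(mirna, g, min_identity = 0), "min_identity")
})

test_that("the external blastn adapter locates the same planted locus as the builtin engine", {
  set.seed(21)
  q <- random_dna_str(80)
  g <- genome_sequence(c(chr1 = paste0(random_dna_str(400), q,
                                       random_dna_str(400))))
  builtin <- best_hit(local_search(q, g, blast_params(engine = "builtin")))
  external <- best_hit(local_search(q, g, blast_params(engine = "blastn")))
  expect_equal(external$chrom, builtin$chrom)
  expect_equal(external$start, builtin$start)
  expect_equal(external$end, builtin$end)
  expect_equal(external$strand, "+")
  expect_equal(external$identity, 100)
  expect_equal(external$subject_seq, q)
})
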