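#' Parameters of the built-in local search engine
#'
#' The built-in engine is a seed-and-extend local aligner in the BLASTn
#' mould: exact word seeding followed by gapped Smith-Waterman extension
#' around each seed cluster. Raw scores S are converted to bit scores via
#' `(lambda * S - ln K) / ln 2`.
#'
#' @param word_size Exact-word seed length (nt).
#' @param match,mismatch Match reward and mismatch penalty.
#' @param gap_open,gap_extend Affine gap costs (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param lambda,K Karlin-Altschul parameters for the bit-score conversion.
#' @param min_bits Hits below this bit score are dropped.
#' @param engine `"builtin"` or `"blastn"` (external binary adapter).
#' @return A list of class `blast_params`.
#' @export
blast_params <- function(word_size = 11L, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2,
                         lambda = 0.625, K = 0.41, min_bits = 20,
                         engine = c("builtin", "blastn")) {
  engine <- match.arg(engine)
  structure(list(word_size = as.integer(word_size), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 min_bits = min_bits, engine = engine),
            class = "blast_params")
}

bits_from_raw <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' Local sequence-similarity search
#'
#' Searches both strands of every chromosome of `subject` for local
#' alignments with `query`. Hits are returned sorted by bit score
#' (descending), ties broken by smaller subject start and then plus strand.
#'
#' @param query Nucleotide string (length >= `word_size`).
#' @param subject A [genome_sequence()] object.
#' @param params A [blast_params()] list.
#' @return A `data.frame` with one hit per row: `query_id`, `chrom`,
#'   `start`, `end`, `strand`, `bit_score`, `identity` (percent),
#'   `coverage` (percent of query), `subject_seq` (hit sequence in query
#'   orientation).
#' @export
local_search <- function(query, subject, params = blast_params()) {
  if (is.null(query) || !nzchar(query)) stop("empty query")
  if (params$engine == "blastn") {
    return(local_search_blastn(query, subject, params))
  }
  if (nchar(query) < params$word_size) {
    stop(sprintf("query shorter than word size (%d)", params$word_size))
  }
  h_chrom <- character(0); h_start <- integer(0); h_end <- integer(0)
  h_strand <- character(0); h_bits <- numeric(0); h_ident <- numeric(0)
  h_cov <- numeric(0); h_seq <- character(0)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else reverse_complement(query)
    qlen <- nchar(q)
    qi <- encode_dna(q)
    for (chrom in names(subject$seqs)) {
      spos <- seed_hits_cpp(qi, subject$enc[[chrom]], params$word_size) + 1L
      if (length(spos) == 0) next
      # cluster seed positions: seeds within one query length belong to the
      # same candidate locus
      grp <- cumsum(c(1L, diff(spos) > qlen))
      for (g in unique(grp)) {
        sp <- spos[grp == g]
        w0 <- max(1L, min(sp) - qlen)
        w1 <- min(subject$lengths[[chrom]],
                  max(sp) + params$word_size - 1L + qlen)
        al <- sw_align_cpp(qi, subject$enc[[chrom]][w0:w1], params$match,
                           params$mismatch, params$gap_open,
                           params$gap_extend)
        if (al$score <= 0) next
        bits <- bits_from_raw(al$score, params)
        if (bits < params$min_bits) next
        sstart <- w0 - 1L + al$sstart      # 0-based genome start
        send <- w0 - 1L + al$send          # 0-based exclusive end
        hit_seq <- substr(subject$seqs[[chrom]], sstart + 1L, send)
        if (strand == "-") hit_seq <- reverse_complement(hit_seq)
        h_chrom <- c(h_chrom, chrom); h_start <- c(h_start, sstart)
        h_end <- c(h_end, send); h_strand <- c(h_strand, strand)
        h_bits <- c(h_bits, bits)
        h_ident <- c(h_ident, 100 * al$nident / al$alen)
        h_cov <- c(h_cov, 100 * (al$qend - al$qstart) / qlen)
        h_seq <- c(h_seq, hit_seq)
      }
    }
  }
  if (length(h_chrom) == 0) return(finalize_hits(list()))
  finalize_hits(list(data.frame(
    query_id = "query", chrom = h_chrom, start = h_start, end = h_end,
    strand = h_strand, bit_score = h_bits, identity = h_ident,
    coverage = h_cov, subject_seq = h_seq, stringsAsFactors = FALSE)))
}

finalize_hits <- function(hits) {
  empty <- data.frame(query_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), bit_score = numeric(),
                      identity = numeric(), coverage = numeric(),
                      subject_seq = character(), stringsAsFactors = FALSE)
  if (length(hits) == 0) return(empty)
  df <- do.call(rbind, hits)
  # deduplicate overlapping hits (e.g. plus/minus of a palindromic locus
  # or adjacent seed clusters): keep the best-scoring one per locus
  df <- df[order(-df$bit_score, df$start, df$strand), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    if (!keep[r]) next
    if (r < nrow(df)) {
      for (r2 in (r + 1L):nrow(df)) {
        if (!keep[r2]) next
        if (df$chrom[r2] == df$chrom[r] &&
            min(df$end[r], df$end[r2]) - max(df$start[r], df$start[r2]) > 0) {
          keep[r2] <- FALSE
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Best hit of a search result
#'
#' The first hit after the documented sort (bit score descending, then
#' subject start, then plus strand), or `NULL` for an empty result.
#'
#' @param hits Hit data frame from [local_search()].
#' @return One-row data frame or `NULL`.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  hits[1, , drop = FALSE]
}

#' Reverse-search confirmation of an ortholog candidate
#'
#' A candidate sequence is accepted if its best hit in the reference
#' genome overlaps the reference pre-miRNA locus (>= 1 nt). This is the
#' reciprocity criterion that separates orthologs from paralogous or
#' spurious matches.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param ref_genome Reference [genome_sequence()].
#' @param mirna One-row miRNA table entry for the reference miRNA.
#' @param params [blast_params()].
#' @return `TRUE` if confirmed.
#' @export
confirm_by_reverse_search <- function(candidate, ref_genome, mirna,
                                      params = blast_params()) {
  if (is.null(candidate) || !nzchar(candidate)) stop("empty candidate")
  bh <- best_hit(local_search(candidate, ref_genome, params))
  if (is.null(bh)) return(FALSE)
  ov <- interval_overlap(gi(bh$chrom, bh$start, bh$end, bh$strand),
                         gi(mirna$chrom, mirna$start, mirna$end, mirna$strand))
  ov >= 1L
}

#' Lift a miRNA annotation over to another assembly
#'
#' Maps the pre-miRNA sequence onto `new_genome` and returns the interval
#' of the best hit passing the identity and query-coverage cutoffs, or
#' `NULL` if no hit qualifies.
#'
#' @param mirna One-row miRNA table entry.
#' @param new_genome Target [genome_sequence()].
#' @param min_identity Minimum percent identity (default 90).
#' @param min_coverage Minimum percent query coverage (default 80).
#' @param params [blast_params()].
#' @return A one-row interval data frame or `NULL`.
#' @export
liftover_mirna <- function(mirna, new_genome, min_identity = 90,
                           min_coverage = 80, params = blast_params()) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)
  hits <- local_search(mirna$sequence, new_genome, params)
  hits <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  bh <- best_hit(hits)
  if (is.null(bh)) return(NULL)
  gi(bh$chrom, bh$start, bh$end, bh$strand)
}

# External engine adapter: runs the blastn binary with tabular output and
# converts it into the same hit data frame as the built-in engine.
local_search_blastn <- function(query, subject, params) {
  if (Sys.which("blastn") == "") stop("blastn binary not found on PATH")
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fa"); sf <- file.path(td, "subject.fa")
  writeLines(c(">query", query), qf)
  write_genome_fasta(subject, sf)
  out <- file.path(td, "hits.tsv")
  fmt <- "6 qseqid sseqid pident qcovs sstart send sstrand bitscore"
  status <- system2("blastn",
                    c("-task", "blastn", "-query", qf, "-subject", sf,
                      "-outfmt", shQuote(fmt), "-out", out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn invocation failed")
  if (!file.exists(out) || file.size(out) == 0) return(finalize_hits(list()))
  df <- utils::read.delim(out, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "qcovs", "sstart", "send",
                 "sstrand", "bitscore")
  hits <- lapply(seq_len(nrow(df)), function(r) {
    minus <- df$sstrand[r] == "minus"
    s0 <- min(df$sstart[r], df$send[r]) - 1L
    e0 <- max(df$sstart[r], df$send[r])
    iv <- gi(df$sseqid[r], s0, e0, if (minus) "-" else "+")
    data.frame(query_id = df$qseqid[r], chrom = iv$chrom, start = iv$start,
               end = iv$end, strand = iv$strand, bit_score = df$bitscore[r],
               identity = df$pident[r], coverage = df$qcovs[r],
               subject_seq = extract_sequence(subject, iv),
               stringsAsFactors = FALSE)
  })
  finalize_hits(hits)
}
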