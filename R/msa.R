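# Multiple sequence alignment and consensus-structure backends for model
# training. The built-in aligner is an iterative star alignment against the
# reference sequence; mafft can be plugged in where the binary is available.

# global pairwise alignment (match +1, mismatch -1, linear gap -2) returning
# the two aligned strings
global_align <- function(a, b) {
  al <- nw_align_cpp(encode_dna(a), encode_dna(b), 1, -1, 2)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  # note: indexing with the raw idx vector would drop the -1 (gap) entries
  # and misalign the columns, so gaps are filled in by logical assignment
  ga <- rep("-", length(al$qidx))
  gb <- rep("-", length(al$sidx))
  ga[al$qidx >= 0] <- ca[al$qidx[al$qidx >= 0] + 1L]
  gb[al$sidx >= 0] <- cb[al$sidx[al$sidx >= 0] + 1L]
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = al$score)
}

# Star alignment of sequences against the first (reference) sequence:
# each sequence is aligned pairwise to the reference and the pairwise
# alignments are merged on the reference coordinate system, with insertion
# columns keyed by the reference position they follow.
star_align <- function(seqs) {
  ref <- seqs[[1]]
  nref <- nchar(ref)
  if (length(seqs) == 1) {
    return(matrix(strsplit(ref, "")[[1]], nrow = 1,
                  dimnames = list(names(seqs)[1], NULL)))
  }
  pw <- lapply(seqs[-1], function(s) global_align(ref, s))
  # max insertions after each reference position (0 = before first)
  ins <- integer(nref + 1L)
  per_aln <- lapply(pw, function(al) {
    ra <- strsplit(al$a, "")[[1]]
    sa <- strsplit(al$b, "")[[1]]
    pos <- integer(length(ra))   # reference position each column follows
    p <- 0L
    for (i in seq_along(ra)) {
      if (ra[i] != "-") p <- p + 1L
      pos[i] <- p
    }
    list(ra = ra, sa = sa, pos = pos)
  })
  for (al in per_aln) {
    gap_runs <- table(factor(al$pos[al$ra == "-"], levels = 0:nref))
    ins <- pmax(ins, as.integer(gap_runs))
  }
  # master column layout: for ref position p (1..nref): one match column,
  # followed by ins[p+1] insertion columns; ins[1] insertion columns lead.
  ncol_total <- nref + sum(ins)
  col_of_match <- integer(nref)  # master column of each ref match position
  ins_start <- integer(nref + 1L) # first master column of insertion block p
  cp <- 0L
  ins_start[1] <- cp + 1L
  cp <- cp + ins[1]
  for (p in seq_len(nref)) {
    cp <- cp + 1L
    col_of_match[p] <- cp
    ins_start[p + 1L] <- cp + 1L
    cp <- cp + ins[p + 1L]
  }
  stopifnot(cp == ncol_total)
  msa <- matrix("-", nrow = length(seqs), ncol = ncol_total,
                dimnames = list(names(seqs), NULL))
  msa[1, col_of_match] <- strsplit(ref, "")[[1]]
  for (si in seq_along(per_aln)) {
    al <- per_aln[[si]]
    used_ins <- integer(nref + 1L)
    for (i in seq_along(al$ra)) {
      if (al$sa[i] == "-") next
      if (al$ra[i] != "-") {
        msa[si + 1L, col_of_match[al$pos[i]]] <- al$sa[i]
      } else {
        p <- al$pos[i]
        msa[si + 1L, ins_start[p + 1L] + used_ins[p + 1L]] <- al$sa[i]
        used_ins[p + 1L] <- used_ins[p + 1L] + 1L
      }
    }
  }
  msa
}

# mafft adapter (external binary); returns the same row-matrix layout
mafft_align <- function(seqs) {
  if (Sys.which("mafft") == "") stop("mafft binary not found on PATH")
  td <- tempfile("mafft"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  inf <- file.path(td, "in.fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), inf)
  out <- system2("mafft", c("--quiet", "--retree", "2", inf), stdout = TRUE)
  recs <- split_fasta_lines(out)
  msa <- do.call(rbind, lapply(recs, function(s) strsplit(toupper(s), "")[[1]]))
  rownames(msa) <- names(recs)
  msa[names(seqs), , drop = FALSE]
}

split_fasta_lines <- function(lines) {
  idx <- grep("^>", lines)
  ids <- sub("^>", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  bounds <- c(idx, length(lines) + 1L)
  seqs <- vapply(seq_along(idx), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, character(1))
  stats::setNames(chartr("Uu", "Tt", seqs), ids)
}

# majority-rule consensus of alignment columns (ties alphabetical; all-gap
# columns yield "-")
column_consensus <- function(msa) {
  apply(msa, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
}

#' Fold an RNA/DNA sequence into a nested secondary structure
#'
#' The built-in folder maximizes Watson-Crick plus G:U base pairs with a
#' minimum loop length (Nussinov recursion); the `"rnafold"` engine
#' delegates to the RNAfold binary (minimum-free-energy structure) where
#' available.
#'
#' @param seq Nucleotide string.
#' @param min_loop Minimum hairpin loop length (built-in engine).
#' @param engine `"builtin"` or `"rnafold"`.
#' @return Integer vector of 1-based partner positions (`NA` = unpaired).
#' @export
fold_sequence <- function(seq, min_loop = 3L,
                          engine = c("builtin", "rnafold")) {
  engine <- match.arg(engine)
  if (engine == "rnafold") {
    if (Sys.which("RNAfold") == "") stop("RNAfold binary not found on PATH")
    out <- system2("RNAfold", c("--noPS"),
                   input = chartr("T", "U", seq), stdout = TRUE)
    db <- strsplit(sub("\\s.*$", "", out[2]), "")[[1]]
    return(dotbracket_to_partners(db))
  }
  partner <- nussinov_cpp(encode_dna(seq), as.integer(min_loop))
  partner <- partner + 1L
  partner[partner == 0L] <- NA_integer_
  partner
}

dotbracket_to_partners <- function(db) {
  partner <- rep(NA_integer_, length(db))
  stack <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}

partners_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  for (i in seq_along(partner)) {
    if (!is.na(partner[i])) db[i] <- if (partner[i] > i) "(" else ")"
  }
  paste(db, collapse = "")
}
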