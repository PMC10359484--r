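#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and RNA (`U`) is converted to DNA (`T`).
#' Record identifiers are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param assembly Assembly label stored in the returned object.
#' @return A [genome_sequence()] object.
#' @export
read_genome_fasta <- function(path, assembly = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop(sprintf("malformed FASTA (line 1 of %s): expected '>' header", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA record id '%s' in %s",
                 ids[duplicated(ids)][1], path))
  }
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad)) {
    stop(sprintf("illegal (non-IUPAC) characters in FASTA record '%s' of %s",
                 ids[bad][1], path))
  }
  names(seqs) <- ids
  genome_sequence(seqs, assembly = assembly)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_sequence()] object.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome$seqs)) {
    writeLines(paste0(">", id), con)
    s <- genome$seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read protein-coding gene annotation from GFF3
#'
#' Features with `type == "gene"` are kept. GFF3 1-based inclusive
#' coordinates are converted to the package-internal 0-based half-open
#' convention, and genes are returned sorted by start within chromosome.
#'
#' @param path Path to a GFF3 file with `ID=` attributes on gene features.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop(sprintf("malformed GFF3 in %s: %s",
                                     path, conditionMessage(e)))
  )
  gr <- gr[gr$type == "gene"]
  ann <- data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(ann$gene_id)) {
    stop(sprintf("duplicate gene id '%s' in %s",
                 ann$gene_id[duplicated(ann$gene_id)][1], path))
  }
  sort_annotation(ann)
}

sort_annotation <- function(ann) {
  ann <- ann[order(ann$chrom, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write gene annotation as GFF3
#'
#' @param ann Annotation data frame (see [read_gene_annotation()]).
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @export
write_gene_annotation <- function(ann, path, source = "mirsynteny") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$chrom, source, ann$start + 1L, ann$end,
                     ann$strand, ann$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# default column names of the miRNA table (MirGeneDB-style, TSV)
mirna_table_columns <- c(
  "mirna_id", "family_id", "chrom", "start", "end", "strand", "sequence",
  "mature_start", "mature_end", "star_start", "star_end",
  "loop_start", "loop_end", "flank5_start", "flank5_end",
  "flank3_start", "flank3_end"
)

#' Read a reference miRNA table
#'
#' A TSV with one pre-miRNA per row: identifiers, genomic interval
#' (0-based half-open), the pre-miRNA sequence in transcribed orientation,
#' and genomic sub-intervals for the mature, star and loop regions plus the
#' 30-nt flanking regions. A `column_map` (new name = file name) allows
#' other dialects to be read.
#'
#' @param path Path to the TSV file.
#' @param column_map Optional named character vector mapping package column
#'   names to the column names used in the file.
#' @return A `data.frame` of class `mirna_table`.
#' @export
read_mirna_table <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(mirna_table_columns[1:7], names(df))
  if (length(missing) > 0) {
    stop(sprintf("miRNA table %s lacks column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  validate_mirna_table(df)
}

#' @export
write_mirna_table <- function(mirnas, path) {
  utils::write.table(mirnas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a miRNA table
#'
#' Checks the structural invariants: sequence length equals interval
#' length, sub-intervals are nested in (or, for flanks, adjacent to) the
#' pre-miRNA interval, and mature and star regions do not overlap.
#'
#' @param df A miRNA table data frame.
#' @return The validated table, classed `mirna_table`.
#' @export
validate_mirna_table <- function(df) {
  if (anyDuplicated(df$mirna_id)) stop("duplicate mirna_id in miRNA table")
  bad <- nchar(df$sequence) != (df$end - df$start)
  if (any(bad)) {
    stop(sprintf("pre-miRNA sequence length mismatch for %s",
                 df$mirna_id[bad][1]))
  }
  for (r in seq_len(nrow(df))) {
    row <- df[r, ]
    for (sub in c("mature", "star", "loop")) {
      s <- row[[paste0(sub, "_start")]]; e <- row[[paste0(sub, "_end")]]
      if (is.na(s) || is.na(e)) next
      if (s < row$start || e > row$end || s >= e) {
        stop(sprintf("%s region of %s not nested in pre-miRNA interval",
                     sub, row$mirna_id))
      }
    }
    # mature and star must not overlap
    if (!any(is.na(c(row$mature_start, row$star_start)))) {
      ov <- min(row$mature_end, row$star_end) -
        max(row$mature_start, row$star_start)
      if (ov > 0) stop(sprintf("mature and star overlap for %s", row$mirna_id))
    }
  }
  class(df) <- c("mirna_table", "data.frame")
  df
}

#' Read a pairwise protein-ortholog table
#'
#' Two-column TSV mapping reference gene ids to core-species gene ids;
#' the mapping must be one-to-one.
#'
#' @param path Path to the TSV (columns `ref_gene`, `core_gene`, no header
#'   required if exactly two columns).
#' @return Named character vector: `names` are reference gene ids, values
#'   core gene ids.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE, comment.char = "#")
  if (identical(tolower(df[1, 1]), "ref_gene")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop(sprintf("ortholog table %s needs two columns", path))
  tab <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (anyDuplicated(names(tab)) || anyDuplicated(tab)) {
    stop(sprintf("ortholog table %s is not one-to-one", path))
  }
  tab
}

#' @export
write_ortholog_table <- function(tab, path) {
  utils::write.table(data.frame(ref_gene = names(tab), core_gene = unname(tab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF file
#'
#' Only the fields needed for diversity analyses are kept: position and
#' the minor allele frequency derived from the INFO `AF` field
#' (`maf = min(AF, 1 - AF)`).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file with an
#'   `AF` INFO field.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based) and `maf`.
#' @export
read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- VariantAnnotation::info(vcf)$AF
  af <- vapply(af, function(x) as.numeric(x)[1], numeric(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    maf = pmin(af, 1 - af),
    stringsAsFactors = FALSE
  )
}

#' @export
write_variants_vcf <- function(variants, path, af = NULL) {
  if (is.null(af)) af <- variants$maf
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\tA\tG\t.\tPASS\tAF=%g",
                  variants$chrom, variants$pos + 1L, af)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a gold-standard miRNA location table
#'
#' TSV with columns `species`, `family_id`, `mirna_id`, `chrom`, `start`,
#' `end`, `strand` (0-based half-open coordinates).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`.
#' @export
read_gold_standard <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_gold_standard
#' @param gold Gold-standard data frame.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(gold, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ortholog predictions
#'
#' `write_predictions_tsv()` stores all prediction fields;
#' `write_predictions_bed()` writes a BED6 track whose score column is the
#' score fraction scaled to 0-1000.
#'
#' @param preds Prediction data frame (see [search_orthologs()]).
#' @param path Output path.
#' @export
write_predictions_tsv <- function(preds, path) {
  utils::write.table(preds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_tsv
#' @export
read_predictions_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_predictions_tsv
#' @export
write_predictions_bed <- function(preds, path) {
  score <- pmin(1000L, as.integer(round(preds$score_fraction * 1000)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   preds$chrom, preds$start, preds$end, preds$mirna_id,
                   score, preds$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read alignment blocks from a MAF file
#'
#' Minimal reader for the multiple-alignment format used by whole-genome
#' alignment tracks; only `a` (block) and `s` (sequence row) lines are
#' interpreted.
#'
#' @param path Path to a MAF file.
#' @return A list of blocks; each block is a `data.frame` with columns
#'   `src` (species or species.chrom), `start`, `size`, `strand`,
#'   `src_size`, `text` (aligned sequence with gaps).
#' @export
read_maf_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur) > 0) {
      blocks[[length(blocks) + 1L]] <- do.call(rbind, cur)
    }
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list()
    } else if (startsWith(ln, "s")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur[[length(cur) + 1L]] <- data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
  }
  flush(cur, blocks)
}
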