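#' Configuration of the clade simulator
#'
#' Defines the evolutionary regime of a simulated clade: a species tree,
#' genomes with conserved protein-coding gene order, and hairpin miRNA
#' loci evolving with substitutions, losses, tandem duplications,
#' whole-genome duplications and gene-order inversions. Substitution rates
#' inside a miRNA locus are scaled per sub-region; by default the mature
#' arm is the most constrained and the flanks evolve at the background
#' rate (`mature <= star <= loop <= flank`), mirroring the diversity
#' ordering observed in real miRNA genes.
#'
#' @param seed Random seed; the full fixture set is a deterministic
#'   function of the configuration.
#' @param n_species Number of extant species (tree tips).
#' @param tree_shape `"balanced"`, `"caterpillar"`, or a Newick string.
#' @param n_genes Protein-coding genes per genome.
#' @param n_mirnas Number of miRNA families (one gene each at planting).
#' @param p_sub Per-branch substitution probability per site.
#' @param p_loss Per-branch probability that a miRNA copy is lost.
#' @param p_dup Per-branch probability of a tandem duplication per copy.
#' @param wgd_nodes Labels of nodes whose stem branch carries a
#'   whole-genome duplication.
#' @param inversions_per_branch Expected number of gene-block inversions
#'   per branch (Poisson).
#' @param mult_mature,mult_star,mult_loop,mult_flank Substitution-rate
#'   multipliers of the miRNA sub-regions.
#' @param frac_intragenic Fraction of miRNAs planted inside a host gene.
#' @param gene_len,igs_len Gene and intergenic segment lengths (nt).
#' @param stem,loop_len Hairpin stem and loop lengths
#'   (`2 * stem + loop_len` must stay within 55-70 nt).
#' @param n_core Number of core species (nearest relatives of the
#'   reference) used for model training.
#' @param gain_nodes Optional named vector (family id pattern `mirXX` ->
#'   node label on the reference lineage) placing family origins below the
#'   root.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_species = 8L,
                              tree_shape = "balanced",
                              n_genes = 500L, n_mirnas = 10L,
                              p_sub = 0.01, p_loss = 0.05, p_dup = 0.01,
                              wgd_nodes = character(0),
                              inversions_per_branch = 1,
                              mult_mature = 0.2, mult_star = 0.5,
                              mult_loop = 1, mult_flank = 1,
                              frac_intragenic = 0.4,
                              gene_len = 300L, igs_len = 250L,
                              stem = 25L, loop_len = 12L,
                              n_core = 4L, gain_nodes = NULL) {
  probs <- c(p_sub = p_sub, p_loss = p_loss, p_dup = p_dup)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  mults <- c(mult_mature, mult_star, mult_loop, mult_flank)
  if (any(mults < 0)) stop("rate multipliers must be >= 0")
  if (!(mult_mature <= mult_star && mult_star <= mult_loop &&
          mult_loop <= mult_flank)) {
    stop("expected mult_mature <= mult_star <= mult_loop <= mult_flank")
  }
  pre_len <- 2L * stem + loop_len
  if (pre_len < 55L || pre_len > 70L) {
    stop("pre-miRNA length (2*stem + loop_len) must lie within 55-70 nt")
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    tree_shape = tree_shape, n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas), p_sub = p_sub, p_loss = p_loss,
    p_dup = p_dup, wgd_nodes = wgd_nodes,
    inversions_per_branch = inversions_per_branch,
    mult_mature = mult_mature, mult_star = mult_star,
    mult_loop = mult_loop, mult_flank = mult_flank,
    frac_intragenic = frac_intragenic, gene_len = as.integer(gene_len),
    igs_len = as.integer(igs_len), stem = as.integer(stem),
    loop_len = as.integer(loop_len), n_core = as.integer(n_core),
    gain_nodes = gain_nodes
  ), class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Generate a pre-miRNA hairpin
#'
#' Random 5' arm and loop; the 3' arm is the reverse complement of the 5'
#' arm with a fraction of G:U wobble pairs. Sub-regions follow the
#' canonical layout: the mature arm covers 5'-arm positions 1-22, the star
#' is its complementary span on the 3' arm, and the loop sits between the
#' arms.
#'
#' @param stem Stem length (>= 22 nt).
#' @param loop_len Loop length; `2 * stem + loop_len` must be 55-70 nt.
#' @param wobble Fraction of stem positions using a G:U pair.
#' @return List with `seq` (transcribed orientation), and 1-based
#'   position pairs `mature`, `star`, `loop`.
#' @export
generate_hairpin <- function(stem = 25L, loop_len = 12L, wobble = 0.1) {
  pre_len <- 2L * stem + loop_len
  if (stem < 22L) stop("stem must be >= 22 nt to host a mature arm")
  if (pre_len < 55L || pre_len > 70L) {
    stop("pre-miRNA length must lie within 55-70 nt")
  }
  arm5 <- sample(BASES, stem, replace = TRUE)
  loop <- sample(BASES, loop_len, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  partner <- comp[arm5]
  wob <- stats::runif(stem) < wobble & arm5 %in% c("G", "T")
  partner[wob] <- ifelse(arm5[wob] == "G", "T", "G")
  arm3 <- rev(partner)   # 3' arm written 5'->3'
  list(
    seq = paste(c(arm5, loop, arm3), collapse = ""),
    mature = c(1L, 22L),
    loop = c(stem + 1L, stem + loop_len),
    star = c(stem + loop_len + (stem - 21L), pre_len)
  )
}

# ---- species tree -----------------------------------------------------------

balanced_newick <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  half <- ceiling(n / 2)
  sprintf("(%s,%s)", balanced_newick(labels[1:half]),
          balanced_newick(labels[(half + 1):n]))
}

caterpillar_newick <- function(labels) {
  out <- labels[length(labels)]
  for (i in rev(seq_len(length(labels) - 1L))) {
    out <- sprintf("(%s,%s)", labels[i], out)
  }
  out
}

sim_tree <- function(config) {
  labels <- sprintf("s%02d", seq_len(config$n_species))
  nwk <- switch(config$tree_shape,
                balanced = paste0(balanced_newick(labels), ";"),
                caterpillar = paste0(caterpillar_newick(labels), ";"),
                config$tree_shape)
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  tree
}

node_label_of <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
}

# ---- segment-level genome representation ------------------------------------

seg_row <- function(type, seq, gene_id = NA_character_, part = NA_integer_,
                    mirna_id = NA_character_, side = NA_character_,
                    strand = "+") {
  data.frame(type = type, gene_id = gene_id, part = part,
             mirna_id = mirna_id, side = side, strand = strand, seq = seq,
             stringsAsFactors = FALSE)
}

build_root_genome <- function(config) {
  n_chrom <- max(1L, ceiling(config$n_genes / 600L))
  genes_per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chrom + 1)))
  gene_counter <- 0L
  chroms <- list()
  for (ci in seq_len(n_chrom)) {
    segs <- list(seg_row("igs", random_dna(config$igs_len)))
    for (g in seq_len(genes_per_chrom[ci])) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%04d", gene_counter)
      segs[[length(segs) + 1L]] <- seg_row(
        "gene", random_dna(config$gene_len), gene_id = gid, part = 1L,
        strand = sample(c("+", "-"), 1))
      segs[[length(segs) + 1L]] <- seg_row("igs", random_dna(config$igs_len))
    }
    chroms[[sprintf("chr%d", ci)]] <- do.call(rbind, segs)
  }
  chroms
}

# plant one miRNA locus; returns the modified chromosome data frame
plant_mirna <- function(segs, at, mid, hairpin, strand, intragenic) {
  locus_fwd <- if (strand == "+") hairpin$seq else
    reverse_complement(hairpin$seq)
  host <- if (intragenic) segs$gene_id[at] else NA_character_
  sideL <- if (strand == "+") "5p" else "3p"
  sideR <- if (strand == "+") "3p" else "5p"
  s <- segs$seq[at]
  n <- nchar(s)
  cut <- floor(n / 2)
  left <- substr(s, 1, cut - 30L)
  fl <- substr(s, cut - 29L, cut)
  fr <- substr(s, cut + 1L, cut + 30L)
  right <- substr(s, cut + 31L, n)
  base <- segs[at, ]
  rows <- rbind(
    transform(base, seq = left),
    seg_row("flank", fl, gene_id = host, mirna_id = mid, side = sideL,
            strand = strand),
    seg_row("mirna", locus_fwd, gene_id = host, mirna_id = mid,
            strand = strand),
    seg_row("flank", fr, gene_id = host, mirna_id = mid, side = sideR,
            strand = strand),
    transform(base, seq = right,
              part = if (intragenic) 2L else base$part)
  )
  rbind(segs[seq_len(at - 1L), ], rows,
        segs[seq(at + 1L, length.out = nrow(segs) - at), ])
}

# ---- mutation ---------------------------------------------------------------

mutate_string <- function(s, rate) {
  n <- nchar(s)
  if (n == 0L || rate <= 0) return(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  chars <- strsplit(s, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# mutate a miRNA locus with per-region rates (regions in transcribed
# orientation)
mutate_mirna_locus <- function(seq_fwd, strand, regions, p_sub, config) {
  tx <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
  chars <- strsplit(tx, "")[[1]]
  n <- length(chars)
  mult <- rep(1, n)
  set_region <- function(mult, span, value) {
    mult[span[1]:span[2]] <- value
    mult
  }
  mult <- set_region(mult, regions$mature, config$mult_mature)
  mult <- set_region(mult, regions$star, config$mult_star)
  mult <- set_region(mult, regions$loop, config$mult_loop)
  hit <- stats::runif(n) < p_sub * mult
  for (p in which(hit)) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  tx2 <- paste(chars, collapse = "")
  if (strand == "+") tx2 else reverse_complement(tx2)
}

mutate_genome <- function(chroms, config, regions_by_mirna) {
  for (nm in names(chroms)) {
    segs <- chroms[[nm]]
    for (r in seq_len(nrow(segs))) {
      type <- segs$type[r]
      if (type == "mirna") {
        fam <- sub("_c\\d+$", "", segs$mirna_id[r])
        segs$seq[r] <- mutate_mirna_locus(
          segs$seq[r], segs$strand[r], regions_by_mirna[[fam]],
          config$p_sub, config)
      } else {
        rate <- if (type == "flank") config$p_sub * config$mult_flank
                else config$p_sub
        segs$seq[r] <- mutate_string(segs$seq[r], rate)
      }
    }
    chroms[[nm]] <- segs
  }
  chroms
}

# ---- structural events ------------------------------------------------------

apply_losses <- function(chroms, config, events) {
  for (nm in names(chroms)) {
    segs <- chroms[[nm]]
    mir_rows <- which(segs$type == "mirna")
    if (length(mir_rows) == 0) next
    lost <- mir_rows[stats::runif(length(mir_rows)) < config$p_loss]
    if (length(lost) == 0) next
    for (r in lost) {
      events$loss <- c(events$loss, segs$mirna_id[r])
    }
    drop <- sort(unique(c(lost)))
    # retype the orphaned flanks as plain intergenic sequence
    for (r in drop) {
      for (fr in c(r - 1L, r + 1L)) {
        if (fr >= 1L && fr <= nrow(segs) && segs$type[fr] == "flank" &&
            identical(segs$mirna_id[fr], segs$mirna_id[r])) {
          segs$type[fr] <- if (is.na(segs$gene_id[fr])) "igs" else "gene"
          segs$mirna_id[fr] <- NA_character_
          segs$side[fr] <- NA_character_
        }
      }
    }
    segs <- segs[-drop, , drop = FALSE]
    chroms[[nm]] <- segs
  }
  list(chroms = chroms, events = events)
}

apply_tandem_dups <- function(chroms, config, events) {
  for (nm in names(chroms)) {
    segs <- chroms[[nm]]
    mir_rows <- which(segs$type == "mirna")
    dup <- mir_rows[stats::runif(length(mir_rows)) < config$p_dup]
    if (length(dup) == 0) next
    for (r in rev(sort(dup))) {
      copy <- segs[r, , drop = FALSE]
      events$dup <- c(events$dup, copy$mirna_id)
      segs <- rbind(segs[seq_len(r), , drop = FALSE], copy,
                    segs[seq(r + 1L, length.out = nrow(segs) - r), ,
                         drop = FALSE])
    }
    chroms[[nm]] <- segs
  }
  list(chroms = chroms, events = events)
}

apply_wgd <- function(chroms) {
  extra <- chroms
  names(extra) <- paste0(names(chroms), "w")
  for (nm in names(extra)) {
    gid <- extra[[nm]]$gene_id
    extra[[nm]]$gene_id <- ifelse(is.na(gid), gid, paste0(gid, "_w"))
  }
  c(chroms, extra)
}

apply_inversions <- function(chroms, config) {
  n_inv <- stats::rpois(1L, config$inversions_per_branch)
  if (n_inv == 0L) return(chroms)
  flip_side <- function(side) {
    ifelse(is.na(side), side, ifelse(side == "5p", "3p", "5p"))
  }
  for (dummy in seq_len(n_inv)) {
    nm <- sample(names(chroms), 1L)
    segs <- chroms[[nm]]
    gene_ids <- unique(segs$gene_id[segs$type == "gene"])
    gene_ids <- gene_ids[!is.na(gene_ids)]
    if (length(gene_ids) < 2L) next
    i <- sample.int(length(gene_ids) - 1L, 1L)
    j <- min(length(gene_ids), i + sample.int(6L, 1L))
    rows_i <- which(segs$gene_id == gene_ids[i])
    rows_j <- which(segs$gene_id == gene_ids[j])
    a <- min(rows_i); b <- max(rows_j)
    block <- segs[a:b, , drop = FALSE]
    block <- block[rev(seq_len(nrow(block))), , drop = FALSE]
    block$seq <- reverse_complement(block$seq)
    flip <- block$type %in% c("gene", "mirna", "flank")
    block$strand[flip] <- ifelse(block$strand[flip] == "+", "-", "+")
    block$side <- flip_side(block$side)
    segs[a:b, ] <- block
    chroms[[nm]] <- segs
  }
  chroms
}

# ---- realization ------------------------------------------------------------

realize_genome <- function(chroms, species) {
  seqs <- vapply(chroms, function(segs) paste(segs$seq, collapse = ""),
                 character(1))
  genome_sequence(seqs, assembly = species)
}

realize_features <- function(chroms) {
  genes <- list()
  mirnas <- list()
  for (nm in names(chroms)) {
    segs <- chroms[[nm]]
    ends <- cumsum(nchar(segs$seq))
    starts <- c(0L, ends[-length(ends)])
    gid <- segs$gene_id
    for (g in unique(gid[!is.na(gid)])) {
      rows <- which(gid == g)
      strand <- segs$strand[rows[segs$type[rows] == "gene"]][1]
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = g, chrom = nm, start = starts[min(rows)],
        end = ends[max(rows)], strand = strand, stringsAsFactors = FALSE)
    }
    for (r in which(segs$type == "mirna")) {
      mirnas[[length(mirnas) + 1L]] <- data.frame(
        mirna_id = segs$mirna_id[r], chrom = nm, start = starts[r],
        end = ends[r], strand = segs$strand[r],
        seq_fwd = segs$seq[r], stringsAsFactors = FALSE)
    }
  }
  list(
    annotation = sort_annotation(do.call(rbind, genes)),
    mirna_loci = if (length(mirnas)) do.call(rbind, mirnas) else NULL
  )
}

# genomic sub-interval of a transcribed-orientation span [t1, t2] (1-based)
tx_span_to_genomic <- function(start, end, strand, span) {
  if (strand == "+") {
    c(start + span[1] - 1L, start + span[2])
  } else {
    c(end - span[2], end - span[1] + 1L)
  }
}

#' Simulate an evolving clade of genomes with planted miRNAs
#'
#' Builds a root genome (conserved gene order, hairpin miRNA loci planted
#' between and within protein-coding genes), evolves it along the species
#' tree with substitutions, miRNA losses, tandem duplications, optional
#' whole-genome duplications and gene-order inversions, and returns
#' per-species bundles plus a ground-truth table. Structural events are
#' suppressed on the root-to-reference lineage so the reference annotation
#' stays single-copy.
#'
#' @param config A [simulation_config()].
#' @return List of class `clade_simulation` with `tree`, `ref_species`,
#'   `core_species`, `species` (per-species list of `genome`,
#'   `annotation`, `orthologs`), `mirnas` (reference miRNA table),
#'   `truth` (per species x miRNA copy table), `gold` (gold-standard
#'   location table), `config`.
#' @export
evolve_clade <- function(config) {
  set.seed(config$seed)
  tree <- sim_tree(config)
  ntip <- ape::Ntip(tree)
  ref_species <- tree$tip.label[1]
  # nodes on the root -> reference path (structural events suppressed there)
  ref_tip <- which(tree$tip.label == ref_species)
  ref_path <- c(ref_tip, phangorn::Ancestors(tree, ref_tip, type = "all"))
  # subtree node sets for family gains
  all_nodes <- seq_len(ntip + tree$Nnode)
  subtree <- lapply(all_nodes, function(nd) {
    if (nd <= ntip) nd else c(nd, unlist(phangorn::Descendants(
      tree, nd, type = "all")))
  })
  label_to_node <- stats::setNames(
    all_nodes, vapply(all_nodes, function(nd) node_label_of(tree, nd),
                      character(1)))
  root <- ntip + 1L

  gain_node_of <- stats::setNames(rep(root, config$n_mirnas),
                                  sprintf("mir%03d", seq_len(config$n_mirnas)))
  if (!is.null(config$gain_nodes)) {
    for (fam in names(config$gain_nodes)) {
      nd <- label_to_node[[config$gain_nodes[[fam]]]]
      if (is.null(nd)) stop("unknown gain node label: ",
                            config$gain_nodes[[fam]])
      if (!(nd %in% ref_path) && nd != root) {
        stop("gain nodes must lie on the root-to-reference lineage")
      }
      gain_node_of[[fam]] <- nd
    }
  }

  # root genome with all miRNAs planted
  chroms <- build_root_genome(config)
  n_intra <- round(config$frac_intragenic * config$n_mirnas)
  regions_by_mirna <- list()
  planted <- 0L
  # candidate planting spots: interior igs segments / genes
  for (fam in names(gain_node_of)) {
    planted <- planted + 1L
    intragenic <- planted <= n_intra
    hp <- generate_hairpin(config$stem, config$loop_len)
    regions_by_mirna[[fam]] <- hp[c("mature", "star", "loop")]
    strand <- sample(c("+", "-"), 1L)
    repeat {
      nm <- sample(names(chroms), 1L)
      segs <- chroms[[nm]]
      if (intragenic) {
        cand <- which(segs$type == "gene" & is.na(segs$mirna_id) &
                        !(segs$gene_id %in% segs$gene_id[segs$type == "mirna"]) &
                        nchar(segs$seq) >= 160L & segs$part == 1L)
        # only genes not already split
        cand <- cand[!segs$gene_id[cand] %in%
                       segs$gene_id[!is.na(segs$gene_id) & segs$part %in% 2L]]
      } else {
        cand <- which(segs$type == "igs" & nchar(segs$seq) >= 160L)
        # avoid terminal segments so anchors exist on both sides
        cand <- setdiff(cand, c(1L, nrow(segs)))
      }
      if (length(cand) == 0) next
      at <- sample(cand, 1L)
      chroms[[nm]] <- plant_mirna(segs, at, fam, hp, strand, intragenic)
      break
    }
  }

  wgd_set <- unname(label_to_node[config$wgd_nodes])
  if (length(config$wgd_nodes) > 0 && anyNA(wgd_set)) {
    stop("unknown WGD node label")
  }

  leaves <- list()
  events_by_mirna <- list(loss = list(), dup = list())

  recurse <- function(node, chroms) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) == 0) {
      leaves[[tree$tip.label[node]]] <<- chroms
      return(invisible(NULL))
    }
    for (child in children) {
      gch <- chroms
      # family gains: drop loci that do not belong in this subtree
      for (fam in names(gain_node_of)) {
        g <- gain_node_of[[fam]]
        if (g == root) next
        if (!(child %in% subtree[[g]]) && !(g %in% subtree[[child]])) {
          for (nm in names(gch)) {
            segs <- gch[[nm]]
            drop <- which(segs$type %in% c("mirna", "flank") &
                            !is.na(segs$mirna_id) & segs$mirna_id == fam)
            if (length(drop) > 0) {
              keep_f <- segs$type[drop] == "flank"
              segs$type[drop[keep_f]] <- ifelse(
                is.na(segs$gene_id[drop[keep_f]]), "igs", "gene")
              segs$mirna_id[drop[keep_f]] <- NA_character_
              segs$side[drop[keep_f]] <- NA_character_
              mirs <- drop[!keep_f]
              if (length(mirs) > 0) segs <- segs[-mirs, , drop = FALSE]
              gch[[nm]] <- segs
            }
          }
        }
      }
      on_ref_path <- child %in% ref_path
      if (!on_ref_path) {
        if (child %in% wgd_set) gch <- apply_wgd(gch)
        res <- apply_losses(gch, config, list(loss = character(0)))
        gch <- res$chroms
        for (mid in res$events$loss) {
          events_by_mirna$loss[[mid]] <<- c(events_by_mirna$loss[[mid]],
                                            node_label_of(tree, child))
        }
        res <- apply_tandem_dups(gch, config, list(dup = character(0)))
        gch <- res$chroms
        gch <- apply_inversions(gch, config)
      }
      gch <- mutate_genome(gch, config, regions_by_mirna)
      recurse(child, gch)
    }
  }
  recurse(root, chroms)

  # reference miRNA table (reference lineage is single-copy by design)
  ref_feat <- realize_features(leaves[[ref_species]])
  ref_loci <- ref_feat$mirna_loci
  mirna_rows <- list()
  for (r in seq_len(nrow(ref_loci))) {
    loc <- ref_loci[r, ]
    fam <- loc$mirna_id
    reg <- regions_by_mirna[[fam]]
    tx <- if (loc$strand == "+") loc$seq_fwd else
      reverse_complement(loc$seq_fwd)
    mt <- tx_span_to_genomic(loc$start, loc$end, loc$strand, reg$mature)
    st <- tx_span_to_genomic(loc$start, loc$end, loc$strand, reg$star)
    lp <- tx_span_to_genomic(loc$start, loc$end, loc$strand, reg$loop)
    f5 <- if (loc$strand == "+") c(loc$start - 30L, loc$start)
          else c(loc$end, loc$end + 30L)
    f3 <- if (loc$strand == "+") c(loc$end, loc$end + 30L)
          else c(loc$start - 30L, loc$start)
    mirna_rows[[r]] <- data.frame(
      mirna_id = fam, family_id = fam, chrom = loc$chrom,
      start = loc$start, end = loc$end, strand = loc$strand, sequence = tx,
      mature_start = mt[1], mature_end = mt[2],
      star_start = st[1], star_end = st[2],
      loop_start = lp[1], loop_end = lp[2],
      flank5_start = f5[1], flank5_end = f5[2],
      flank3_start = f3[1], flank3_end = f3[2], stringsAsFactors = FALSE)
  }
  mirnas <- validate_mirna_table(do.call(rbind, mirna_rows))

  ref_seed <- function(fam, tx) {
    reg <- regions_by_mirna[[fam]]
    substr(tx, reg$mature[1] + 1L, reg$mature[1] + 7L)
  }
  ref_seeds <- stats::setNames(
    vapply(seq_len(nrow(mirnas)),
           function(r) ref_seed(mirnas$mirna_id[r], mirnas$sequence[r]),
           character(1)),
    mirnas$mirna_id)

  # per-species bundles and truth
  species <- list()
  truth_rows <- list()
  gold_rows <- list()
  ref_gene_ids <- ref_feat$annotation$gene_id
  for (sp in tree$tip.label) {
    feat <- realize_features(leaves[[sp]])
    genome <- realize_genome(leaves[[sp]], sp)
    shared <- intersect(ref_gene_ids, feat$annotation$gene_id)
    orthologs <- stats::setNames(shared, shared)
    species[[sp]] <- list(genome = genome, annotation = feat$annotation,
                          orthologs = orthologs)
    loci <- feat$mirna_loci
    for (fam in names(gain_node_of)) {
      rows <- if (is.null(loci)) integer(0) else which(loci$mirna_id == fam)
      if (length(rows) == 0) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          species = sp, mirna_id = fam, family_id = fam, present = FALSE,
          copy = 0L, chrom = NA_character_, start = NA_integer_,
          end = NA_integer_, strand = NA_character_,
          seed_identical = NA,
          gain_node = node_label_of(tree, gain_node_of[[fam]]),
          loss_nodes = paste(events_by_mirna$loss[[fam]], collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      for (ci in seq_along(rows)) {
        loc <- loci[rows[ci], ]
        tx <- if (loc$strand == "+") loc$seq_fwd else
          reverse_complement(loc$seq_fwd)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          species = sp, mirna_id = fam, family_id = fam, present = TRUE,
          copy = ci, chrom = loc$chrom, start = loc$start, end = loc$end,
          strand = loc$strand,
          seed_identical = ref_seed(fam, tx) == ref_seeds[[fam]],
          gain_node = node_label_of(tree, gain_node_of[[fam]]),
          loss_nodes = paste(events_by_mirna$loss[[fam]], collapse = ";"),
          stringsAsFactors = FALSE)
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          species = sp, family_id = fam, mirna_id = fam, chrom = loc$chrom,
          start = loc$start, end = loc$end, strand = loc$strand,
          stringsAsFactors = FALSE)
      }
    }
  }

  # core species: nearest relatives of the reference
  coph <- ape::cophenetic.phylo(tree)[ref_species, ]
  others <- setdiff(tree$tip.label, ref_species)
  core_species <- others[order(coph[others])][seq_len(
    min(config$n_core, length(others)))]

  structure(list(
    tree = tree, ref_species = ref_species, core_species = core_species,
    species = species, mirnas = mirnas,
    truth = do.call(rbind, truth_rows), gold = do.call(rbind, gold_rows),
    regions = regions_by_mirna, config = config
  ), class = "clade_simulation")
}

#' @export
print.clade_simulation <- function(x, ...) {
  cat(sprintf(
    "<clade_simulation> %d species, %d miRNA families, reference '%s'\n",
    length(x$species), x$config$n_mirnas, x$ref_species))
  cat(sprintf("  %d present copies across species\n", sum(x$truth$present)))
  invisible(x)
}

#' Reference and core bundles of a simulated clade
#'
#' Convenience accessors for the pipeline: `sim_reference_bundle()`
#' returns the reference bundle (genome, annotation, miRNA table);
#' `sim_core_bundles()` the named list of core bundles.
#'
#' @param sim An [evolve_clade()] result.
#' @return Bundle list(s).
#' @export
sim_reference_bundle <- function(sim) {
  list(genome = sim$species[[sim$ref_species]]$genome,
       annotation = sim$species[[sim$ref_species]]$annotation,
       mirnas = sim$mirnas)
}

#' @rdname sim_reference_bundle
#' @export
sim_core_bundles <- function(sim) {
  sim$species[sim$core_species]
}

#' Write a simulated clade to disk in the standard formats
#'
#' FASTA genomes, GFF3 annotations, ortholog TSVs, the reference miRNA
#' table, the truth table and the gold-standard table.
#'
#' @param sim An [evolve_clade()] result.
#' @param dir Output directory (created if needed).
#' @export
write_clade_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$species)) {
    b <- sim$species[[sp]]
    write_genome_fasta(b$genome, file.path(dir, paste0(sp, ".fa")))
    write_gene_annotation(b$annotation, file.path(dir, paste0(sp, ".gff3")))
    write_ortholog_table(b$orthologs,
                         file.path(dir, paste0(sp, ".orthologs.tsv")))
  }
  write_mirna_table(sim$mirnas, file.path(dir, "reference_mirnas.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gold_standard(sim$gold, file.path(dir, "gold.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}

#' Emit a deterministic variant table over region classes
#'
#' Places variants at evenly spaced positions within each region class at
#' the configured per-kb density, and assigns minor allele frequencies
#' according to the given bin weights (representative MAFs per bin), so
#' that densities and MAF fractions are recovered exactly.
#'
#' @param classes Named list of [region_class()] objects (assumed
#'   disjoint).
#' @param densities Named numeric vector: SNPs per kb per class (names
#'   matching `classes`).
#' @param maf_weights Numeric length-3 vector of rare/uncommon/common bin
#'   weights (summing to 1).
#' @return List with `variants` (data frame `chrom`, `pos`, `maf`,
#'   `class`) and `expected` (named vector of exact densities implied by
#'   the integer variant counts).
#' @export
emit_variants <- function(classes, densities,
                          maf_weights = c(rare = 0.5, uncommon = 0.3,
                                          common = 0.2)) {
  stopifnot(all(names(classes) %in% names(densities)))
  maf_rep <- c(5e-05, 0.005, 0.1)
  out <- list()
  expected <- stats::setNames(numeric(length(classes)), names(classes))
  for (nm in names(classes)) {
    rc <- classes[[nm]]
    len <- rc$total_length
    n <- round(densities[[nm]] * len / 1000)
    expected[[nm]] <- 1000 * n / len
    if (n == 0) next
    # evenly spaced offsets in the concatenated class coordinate space
    offs <- floor(seq(0, len - 1, length.out = n))
    iv_len <- rc$intervals$end - rc$intervals$start
    iv_cum <- cumsum(iv_len)
    iv_idx <- findInterval(offs, c(0, iv_cum), rightmost.closed = FALSE)
    local <- offs - c(0, iv_cum)[iv_idx]
    counts <- diff(round(cumsum(c(0, maf_weights / sum(maf_weights))) * n))
    maf <- rep(maf_rep, counts)
    out[[nm]] <- data.frame(
      chrom = rc$intervals$chrom[iv_idx],
      pos = rc$intervals$start[iv_idx] + local,
      maf = maf[seq_len(n)], class = nm, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, out)
  rownames(variants) <- NULL
  list(variants = variants, expected = expected)
}
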