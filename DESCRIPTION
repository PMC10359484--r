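Package: mirsynteny
Title: Synteny-Informed Identification of miRNA Orthologs in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted search for microRNA (miRNA) orthologs in annotated or
    unannotated genome assemblies. Positional orthologs of a reference
    pre-miRNA are collected from closely related core species using
    protein-coding genes as microsynteny anchors and a reciprocal best-hit
    criterion, aligned, and used to train a per-miRNA sequence-plus-structure
    profile model (a compact covariance-model analogue). Target genomes are
    then scanned with the trained model; hits reaching at least half of the
    reference sequence's own model score and confirmed by a reverse search in
    the reference genome are reported as (co-)orthologs. The package also
    provides benchmarking against gold-standard annotations, phylogenetic
    profiling with family-age dating and whole-genome-duplication detection
    from co-ortholog counts, supermatrix construction for phylogenomics,
    SNP-density contrasts between miRNA sub-regions and other genomic region
    classes, and a seeded simulator of evolving genome clades with planted
    hairpin miRNAs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    ape,
    phangorn,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
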