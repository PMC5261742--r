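Package: apomacc
Title: Mutation Accumulation Contrasts Between Sexual and Apomictic Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify deleterious mutation accumulation in asexual
    (apomictic) lineages relative to their sympatric sexual relatives from
    resequencing data. Implements diversity and substitution statistics
    stratified by phylogenetic constraint class (0-fold, 4-fold, conserved
    coding and non-coding sites), constrained-to-neutral substitution ratios
    with exact and large-sample tests, hybrid-origin inference from
    maximum-likelihood five-taxon haplotype trees under a GTR+Gamma model,
    parsimony assignment of derived mutations to branches, and terminal-branch
    contrasts testing for relaxed purifying selection. A seeded synthetic-cohort
    simulator with a complete truth log makes every stage verifiable without
    access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
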