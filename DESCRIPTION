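Package: cagmir
Title: Design and Characterization of CAG-Repeat-Targeting Artificial miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing allele-selective artificial miRNA guide
    strands against expanded CAG repeats and for characterizing their
    behaviour. Implements substitution-variant generation and mismatch
    profiling of guides against trinucleotide-repeat targets, exhaustive
    mismatch-budget (Hamming) off-target scanning of genome and
    transcriptome sequences with locus merging, region annotation and
    variant ranking, classification of small-RNA-seq reads into hairpin
    processing products (arm assignment, 5'-start-site isomiR grouping,
    strand bias, length distribution, abundance relative to the most
    highly expressed endogenous miRNAs), and an expression-restoration
    concordance statistic over paired differential-expression tables.
    Includes seeded synthetic-data generators with ground-truth tables
    for every pipeline stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
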