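Package: cresig
Title: Core CREB Target Signatures from Stimulated Transcriptomes
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for extracting cell-type-specific CREB core
    signatures from stimulated transcriptome data: empirical-Bayes moderated
    differential expression, TRAP first-quartile filtration, binned CRE-motif
    over-representation profiling with position weight matrices, pre-ranked
    GSEA with a gene-set-permutation null, hypergeometric GO enrichment with
    kappa term grouping, and multi-condition core-signature extraction with
    cross-cell-type comparison. Includes a synthetic-study generator that
    plants a known regulon so that every stage has a recoverable ground
    truth, plus readers and writers for TSV, GMT, RNK, FASTA and
    JASPAR/TRANSFAC matrix formats and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
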