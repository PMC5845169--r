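Package: umikit
Title: Error-Correcting Cell Barcodes and UMI-Based Expression Analysis
    for Plate-Based Single-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Plate-seq", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational core of plate-based, cell-barcoded
    single-cell RNA-seq with unique molecular identifiers (UMIs). Designs
    DNA cell-barcode sets with a guaranteed minimum Sequence-Levenshtein
    distance so that up to two sequencing errors (substitution, insertion,
    or deletion) per barcode can be corrected; demultiplexes and
    error-corrects barcoded reads; collapses reads into a digital
    expression matrix of UMI counts; computes quantitative benchmarks
    (UMI conversion efficiency, ERCC spike-in capture efficiency, and the
    spike-in copy number at 50% detection probability); tests genes for
    differential expression between clusters with a deviance-based
    likelihood-ratio test and for cluster enrichment with exact binomial
    tests; classifies within-cell-type variable genes into cell-cycle
    associated and cycle-independent groups using flow-cytometry DNA
    content; and simulates ground-truthed reads, count tables, and flow
    metadata so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    data.table,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    S4Vectors,
    MASS,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
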