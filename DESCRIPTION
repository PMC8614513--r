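Package: psgscan
Title: Branch-Site Positive-Selection Scans on Primate Ortholog Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protein-coding genes under episodic positive selection
    on designated branches of a primate species tree. Implements a codon
    substitution model with site-class mixtures (branch-site test),
    likelihood-ratio tests, Bayes empirical Bayes identification of selected
    sites, a selection-relaxation test, a four-stage false-positive filter
    cascade (alignment gaps, column confidence scores, relaxation), population
    fixation calling of selected codons from variant tables, tissue-specificity
    comparison of selected genes against their closest paralogs, and Fisher
    exact enrichment tests. Ships a synthetic-data generator that emulates
    every pipeline input so the whole scan is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
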