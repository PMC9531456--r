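Package: epimark
Title: Peak Calling, Chromatin-State Discovery and Regulatory-Element
    Integration for Sparse-Background Histone-Mark Profiling
Version: 0.1.0
Authors@R:
    person("epimark", "developers", email = "epimark@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing CUT&Tag-style coverage
    profiles of histone post-translational modifications together with
    matched RNA-seq expression. Provides SEACR-style signal-block peak
    calling for sparse-background tracks, blacklist filtering and union
    (master) peak lists, region quantification with CPM/RPKM
    normalisation, base-pair overlap fold-enrichment statistics,
    multivariate Bernoulli hidden Markov model chromatin-state
    segmentation over 200 bp binarized bins (including a one-mark
    across-tissues mode), combinatorial promoter/enhancer marking
    classification integrated with gene expression, distal
    enhancer-to-nearest-gene linkage, and pairwise differential marking
    with a negative-binomial exact test. A synthetic-data generator
    plants promoter/enhancer occupancy structure and mark-coupled
    expression so that every statistical procedure can be exercised and
    validated against ground truth on a toy genome.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
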