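Package: longsig
Title: Cross-Species Transcriptomic Signatures of Longevity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-transcriptomics pipeline for detecting gene-expression
    correlates of lifespan across related species. From a gene-by-species
    ortholog read-count matrix, a time-calibrated phylogeny, and life-history
    traits it produces TMM-corrected log-RPKM standardized expression,
    neighbor-joining expression phylograms with gene bootstrap, Ornstein-
    Uhlenbeck divergence-plateau fits with bootstrap confidence intervals and
    species jackknife, per-gene phylogenetic-signal statistics (Pagel's lambda,
    Blomberg's K) and Brownian-motion versus multi-optimum Ornstein-Uhlenbeck
    model classification, phylogenetic generalized least-squares regression of
    expression on log lifespan under four residual-covariance models with
    maximum-likelihood model selection, and direction-concordance tests of the
    resulting longevity signature against lifespan-intervention differential-
    expression tables. A seeded synthetic-data generator reproduces the
    statistical structure the pipeline assumes, with ground-truth labels for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
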