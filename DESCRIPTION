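Package: oncomap
Title: Meta-Analysis of Tissue-Independent Cancer Expression Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of large annotated gene expression
    compendia to identify genes whose expression changes with disease status
    across many tissues of origin. Provides an annotated expression container
    built on SummarizedExperiment, group-level similarity mapping and
    hierarchical clustering, principal-component maps, between-group variance
    screening, a per-probeset crossed mixed-effects linear model of disease
    status fitted by restricted maximum likelihood with an approximate t test,
    within-tissue label-permutation inference with a plug-in false discovery
    rate estimator, hypergeometric gene-list validation, and a synthetic-data
    generator with known ground truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
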