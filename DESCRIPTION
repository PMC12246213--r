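Package: bnrisk
Title: Exact Bayesian Network Risk Estimation for Binary Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns exact Bayesian networks over binary clinical and
    genetic variables (Silander-Myllymaki dynamic programming with BIC
    scoring), fits conditional probability tables with zero-state
    smoothing, and answers exact conditional-probability queries by
    network propagation.  On top of the fitted networks it computes
    absolute and relative risk ratios with bootstrap confidence
    intervals obtained by resampling the cohort and re-learning the
    network structure in every replicate.  Includes K-nearest-neighbour
    imputation and collinearity screening for binary cohort matrices, a
    synthetic cohort simulator driven by a ground-truth network with
    exact enumeration oracles, and a gradient-boosted multiclass
    phenotype classifier for hierarchical cardiac phenotype codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
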