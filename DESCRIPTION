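Package: pseudodiff
Title: Pseudotime-Resolved Differential Abundance, Expression and Gene-Module
    Analysis Across Samples
Version: 0.1.0
Authors@R:
    person("Maintainer", "Pseudodiff", email = "maintainer@pseudodiff.org",
           role = c("aut", "cre"))
Description: A trajectory-centric toolkit for multi-sample single-cell
    differentiation analysis. Builds KNN-graph cell neighborhoods, tests
    per-neighborhood differential abundance and pseudobulk differential
    expression between groups with a negative-binomial GLM, controls a
    density-weighted spatial FDR, projects neighborhoods onto pseudotime
    intervals and scores each interval with a binomial test against a
    permutation-estimated null acceptance rate. Discovers pseudotemporal gene
    modules that recur across trajectories by non-negative matrix
    factorization of interval-level expression followed by pooled factor
    clustering, with activity scoring, conservation and covariate tests.
    Includes pseudotemporal gene attributes (correlation, peak, expression),
    common-pseudotime transfer by gradient-boosted regression trees,
    classifier-based trajectory-bin similarity and merging, and a seeded
    multi-sample negative-binomial trajectory simulator so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
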