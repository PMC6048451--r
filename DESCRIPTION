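Package: rewirekit
Title: Transcriptional Network Rewiring Analysis
Version: 0.1.0
Authors@R:
    person("rewirekit", "developers", email = "rewirekit@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterising transcriptional network
    rewiring: changes in the correlation structure among genes between
    biological states that need not be accompanied by mean-expression
    changes. Provides unsupervised Gaussian mixture clustering of samples
    with parametric-bootstrap significance for mean-equality,
    correlation-equality and model-selection statistics; supervised
    correlation-matrix equivalence tests (Steiger and Jennrich) with
    label-permutation nulls; thresholded correlation-network construction
    with degree, closeness, betweenness and eigenvector centralities,
    consensus hub calling and drug-gene interaction mapping; topological
    overlap module detection with cross-group module matching, permutation
    overlap nulls and per-module rewiring tests; and a synthetic-data
    generator that plants rewiring (equal means, unequal correlations),
    hub genes and mutation labels so that every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
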