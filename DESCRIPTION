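Package: ccbayes
Title: Consensus Clustering for Sampling-Based Bayesian Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble ("consensus") clustering built from many deliberately
    short MCMC chains of an overfitted Bayesian mixture model. Each chain is
    initialised from a prior draw on partitions, run for a small fixed number
    of Gibbs sweeps, and its final partition collected; the ensemble is
    compiled into a consensus matrix from which a point clustering is derived
    by maximising the posterior expected adjusted Rand index. Includes a
    depth/width stability heuristic for sizing the ensemble, long-chain
    convergence diagnostics (Geweke Z-scores with Shapiro-Wilk screening,
    classic and rank-normalised split R-hat, pooled posterior similarity
    matrices), a finite-mixture simulation engine with irrelevant features,
    an EM + BIC Gaussian mixture baseline, and exact small-instance oracles
    (posterior enumeration, exhaustive partition search) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    mclust
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
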