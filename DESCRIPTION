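Package: gtbart
Title: Bayesian Regression Trees for Group Testing Data
Version: 0.1.0
Authors@R:
    person("gtbart", "developers", email = "gtbart@example.org", role = c("aut", "cre"))
Description: Regression analysis of group (pooled) testing data with a
    Bayesian additive regression trees (BART) model for the individual-level
    probability of disease.  Test responses may come from any pooling
    protocol (individual testing, master pool testing, two-stage Dorfman
    testing, or arbitrary, possibly overlapping pools), may be misclassified,
    and assay sensitivities and specificities can be estimated per test
    stratum with conjugate beta updates.  Inference uses a two-stage data
    augmentation Gibbs sampler: latent individual statuses, truncated-normal
    probit latents, Bayesian backfitting of the tree ensemble, and beta
    draws for the accuracy parameters.  Includes protocol simulators, a
    first-order Bayesian probit GLM comparator fitted with the same
    augmentation, variable inclusion proportions, AUC/coverage summaries,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
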