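Package: lfns
Title: Likelihood-Free Nested Sampling for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian parameter inference and evidence estimation for
    stochastic chemical reaction networks with intractable likelihoods.
    Implements likelihood-free nested sampling on the joint prior of a
    parameter vector and one realization of an unbiased particle-filter
    likelihood estimator, with constrained-prior proposal sampling via
    Gaussian-mixture or ellipsoid density estimates, a dead-plus-live-point
    evidence estimator, a closed-form estimator variance with its lower
    bound under the Beta shrinkage model, and the resulting termination
    criterion. Includes an exact Gillespie simulator, a finite state
    projection likelihood oracle for small networks, and particle MCMC and
    ABC-SMC reference baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    mclust,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
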