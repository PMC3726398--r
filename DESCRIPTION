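Package: bvsamra
Title: Bayesian Variable Selection for Modular Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the directed topology of a biochemical network from
    steady-state responses to perturbation experiments. Implements a
    Bayesian variable selection formulation of Modular Response Analysis
    (MRA): spike-and-slab priors on connection coefficients with a
    ridge-stabilized g-prior slab, analytic marginalization over
    coefficients and noise variance, and componentwise Gibbs sampling (or
    exhaustive enumeration for small networks) over binary edge
    indicators. Also provides total-least-squares and Monte-Carlo
    stochastic MRA baselines, a steady-state perturbation simulator with
    intrinsic (SDE) and log-linear measurement noise, and ROC/PR
    evaluation of inferred networks.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
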