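Package: chankin
Title: Kinetic Modeling of Ligand-Gated Ion Channel Activation Under
    Diffusion-Limited Solution Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and global fitting of Markov gating schemes for
    ligand-gated ion channels driven by realistic concentration protocols.
    Models the diffusion-limited time course of the ligand concentration at
    a membrane patch inside a pipette tip (full series solution of the
    one-dimensional diffusion equation and its delayed-exponential
    approximation), calibrates the exchange time constant from potassium
    concentration-jump currents, and corrects nominal pulse protocols
    accordingly. Sequential binding-and-gating schemes with independent or
    cooperative binding steps are propagated exactly on piecewise-constant
    concentration segments via the matrix exponential of the Q-matrix, with
    stochastic simulation of finite channel populations. Global
    least-squares fitting with the exchange-aware forward model yields
    parameter standard errors, covariance and correlation matrices, and
    reduced summed-squared-residual model ranking; Hill fits of
    concentration-activation relationships are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
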