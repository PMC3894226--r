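Package: binnet
Title: Correlation Structure of Finite Recurrent Binary-Neuron Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analytical theory for pairwise zero-lag correlations
    in finite recurrent networks of stochastic binary neurons. A local
    excitatory-inhibitory network is driven by a finite external population,
    so that pairs of neurons share afferents both locally and externally. The
    package solves the self-consistent Gaussian mean-field equations for the
    stationary activities, the linearized system for population-averaged
    pairwise covariances (including the covariance between local neurons and
    the external drive), an iterative scheme feeding finite-size correlations
    back into the input statistics, the moment equations for networks with
    binomially distributed in-degrees, and the infinite-size limits for
    invertible and degenerate (homogeneous) effective connectivity, including
    the perfect-tracking comparison prediction. A fast event-bucketed
    asynchronous simulator of the Glauber-type binary dynamics cross-validates
    every analytical prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
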