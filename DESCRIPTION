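Package: mprcnet
Title: Macroscopic Phase-Resetting Curves for Renewal Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing the macroscopic phase-resetting curve (mPRC) of
    collective oscillations that emerge in networks of renewal (escape-rate)
    spiking neurons. The population is described by the refractory-density
    (age-structured, von Foerster) transport equation, integrated along
    characteristics. The package provides hazard-rate models and their
    interspike-interval duals, the asynchronous steady state and the
    characteristic equation of the linearised operator with Hopf-boundary
    tracing, a backward adjoint solver with the 2*pi/T normalisation whose
    synaptic component is the mPRC, direct-perturbation PRC measurement on both
    the mean-field and finite stochastic networks, and weakly-coupled-oscillator
    interaction (H/G) functions predicting phase locking of two delayed-coupled
    circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
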