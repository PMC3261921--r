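Package: ipsense
Title: Sensitivity Analysis of Intrinsic Plasticity Effects on Neuronal Rate Coding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how plasticity of a generic voltage-gated conductance reshapes a
    neuron's frequency-current (f-I) relation. Provides a conductance-based single-compartment
    Hodgkin-Huxley simulator with stochastic background synaptic drive, estimation of the
    current threshold and inverse gain of f-I curves, threshold and inverse-gain sensitivities
    to the maximal conductance with parameter-plane sweeps, deterministic integrate-and-fire
    sensitivity theories, generalization to kinetic parameters, and a homeostatic intrinsic
    plasticity loop coupling a high-threshold calcium current to a kinase/phosphatase cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
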