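Package: spikesnr
Title: Optimal Coincidence Detection of Spatiotemporal Spike Patterns
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic signal-to-noise ratio (SNR) theory for a leaky
    integrate-and-fire (LIF) neuron detecting multiple repeating
    spatiotemporal spike patterns embedded in Poisson background activity.
    Provides the closed-form expected SNR of a threshold-free LIF with
    unitary synapses, its constrained maximization over the membrane time
    constant and the pattern-subsection duration, generators for frozen
    Poisson patterns with per-presentation jitter, a clock-based LIF
    simulator with adaptive threshold and multiplicative all-to-all STDP
    with homeostatic depression, and the numerical experiments showing
    that STDP-learned detectors approach the theoretical optimum.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
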