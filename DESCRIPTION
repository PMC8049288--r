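Package: oscflow
Title: Signal Transmission and Information Flow Between Delay-Coupled
    Oscillating Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one or two populations of Hodgkin-Huxley neurons
    (excitatory/inhibitory, conductance-based double-exponential synapses)
    coupled by delayed long-range excitatory projections, and quantifies how
    the axonal transmission delay and the detuning of the populations'
    natural oscillation frequencies regulate signal transmission and the
    direction of information flow.  Provides the analysis layer (Gaussian
    multi-unit activity, coherency index, zero-lag cross-covariance, delayed
    mutual information and net information flow, population and non-local
    phase response curves, phase-locking maps), a matching two-oscillator
    phase-reduction theory (locked phase, stability, pulse transmission,
    slow-signal response function and transmission imbalance) with a seeded
    delay-coupled Kuramoto simulator, deterministic test fixtures with known
    ground truth, and config-driven sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
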