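Package: sparsemotor
Title: Sparse-Coding Threshold-Linear Networks for Sensorimotor
    Transformation
Version: 0.1.0
Authors@R:
    person("sparsemotor", "developers", email = "sparsemotor@example.org",
           role = c("aut", "cre"))
Description: Simulates visually guided wrist movements under multiple
    forearm postures with a threshold-linear neural network whose coding
    sparseness is controlled by a single threshold parameter at fixed
    metabolic cost.  Provides the gradient learning rule for
    neuron-to-muscle weights with muscle rectification, sweeps over the
    threshold to locate the error-optimal sparseness, principal-component
    analysis of population activity, generalization tests on novel
    targets, classification of tuning modulation as additive or
    multiplicative (gain-field-like), and comparison networks with
    adaptable sensory weights and tanh activation.  Includes
    finite-difference gradient oracles and deterministic fixtures for
    validation, plus a config-driven command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
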