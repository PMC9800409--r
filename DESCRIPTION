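Package: beqbn
Title: Biased Entangled Quantum-Like Bayesian Networks for Two-Stage Binary Decisions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts human choice probabilities in two-stage binary decision
    tasks under uncertainty using a quantum-like Bayesian network with an
    entanglement-based interference term and a bias potential for unequal
    parent priors. Implements the classical total-probability baseline, the
    quantum-like witness and concurrence-to-entropy chain, a configurable
    predictor resolving the model's documented ambiguities, and an evaluation
    harness with the prisoner's-dilemma and face-categorization benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
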