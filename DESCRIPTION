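Package: ncmsim
Title: Neutrosophic Cognitive Map Simulation of Regulatory Knowledge Networks
Version: 0.1.0
Authors@R:
    person("ncmsim", "Developers", email = "ncmsim@example.org",
           role = c("aut", "cre"))
Description: Simulates qualitative gene-regulatory knowledge maps encoded as
    sparse signed (and optionally indeterminate, "neutrosophic") NxN
    relationship matrices. State vectors are iterated by sparse vector-matrix
    multiplication followed by Elliott squashing, with optional locked
    (clamped) nodes, until the mean squared error between successive states
    falls below a tolerance; converged states are classified into
    expressed/repressed calls and scored against expected outcome panels with
    an exact binomial test under a bias-adjusted null reflecting the network's
    positive-edge fraction. Includes synthetic map generators with known
    degree/sign structure and analytically planted attractors, a hand-written
    stem-cell reprogramming toy fixture, and a command-line harness for
    reproducible simulate/validate/stats/generate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
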