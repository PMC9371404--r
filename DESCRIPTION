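Package: assoclearn
Title: Simulation of Molecular Circuits for Associative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and qualitative classification of
    Hill-equation gene-circuit models of associative (Pavlovian) learning.
    Implements a Hebbian-style weight-molecule circuit and a
    forced-dissociation circuit (plus a reduced variant) in dimensional and
    dimensionless form, rectangular pulse-train stimulus protocols, fixed-step
    forward-Euler and classical Runge-Kutta integrators with step-refinement
    convergence checks, per-event response-peak extraction, and classifiers
    for learning formation, reinforcement, forced dissociation, baseline
    return and conditioning dominance, including Hill-coefficient sweeps and
    single-parameter perturbation studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
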