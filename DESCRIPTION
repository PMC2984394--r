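Package: fihcomp
Title: Kinetic Modelling of FIH Sequestration by Ankyrin Repeat Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dimensionless rate-equation models of oxygen-dependent HIF-alpha
    hydroxylation by the prolyl hydroxylases (PHD) and factor inhibiting HIF
    (FIH), with competitive sequestration of FIH by the cellular pool of
    ankyrin-repeat domain (ARD) proteins. Implements a three-variable full
    model with tight-binding (free-substrate) kinetics and two skeleton
    models, time-course integration under piecewise-constant oxygen
    protocols, steady-state computation by relaxation, and derived response
    metrics: oxygen thresholds for FIH release, apparent Hill exponents
    (ultrasensitivity), interior peaks of CAD-hydroxylated HIF-alpha, and
    reoxygenation-delay memory maps. Also provides an ankyrin-repeat motif
    toolkit: database parsing, loop-asparagine and L(-8)N motif
    classification, consensus and position-frequency summaries, and a seeded
    synthetic repeat-database generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
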