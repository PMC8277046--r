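Package: glucodyn
Title: Glucose-Limited Tumor Cell Growth Kinetics: Simulation, Calibration and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modeling of in vitro tumor cell growth under glucose
    limitation. Implements a three-member family of coupled ordinary
    differential equation models for live-cell confluence, dead-cell
    confluence and glucose concentration, with glucose- and time-dependent
    state functions partitioning cell fate between proliferation and
    starvation death, plus a bystander death term driven by the dead-cell
    fraction. Provides a synthetic time-resolved microscopy cohort generator,
    multistart nonlinear least-squares calibration under local, global and
    mixed parameter-sharing scenarios with linearized confidence intervals,
    small-sample AICc model selection, fitting of phenomenological bystander
    death-rate laws against initial glucose and confluence, and a repeated
    train/validate pipeline with Monte-Carlo prediction bands and accuracy
    scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
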