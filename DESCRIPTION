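Package: scpmech
Title: Hyper-Viscoelastic Material Models and Calibration for the Spinal Cord-Pia Complex
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuum-level constitutive models for spinal cord parenchyma
    (one-term Ogden hyperelasticity combined with quasi-linear
    viscoelasticity through a normalized Prony series) and pia mater
    (single-term Ogden), together with the tooling needed to calibrate and
    evaluate them at desk scale: homogeneous single-element ramp
    simulations at experimental strain rates, a constrained equal-weighted
    multi-rate parameter identification routine, a reduced-order
    one-degree-of-freedom pellet impact surrogate, trajectory phase
    segmentation and averaging, goodness-of-fit metrics (R-squared, RMSE,
    a two-component CORA rating, Richardson extrapolation), and seeded
    synthetic-data generators that emulate the ex-vivo tissue experiments
    the models are built from.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
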