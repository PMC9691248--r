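Package: ilextract
Title: Ionic-Liquid Biphasic Extraction Analytics for Heme Depletion and
    Cotinine ELISA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of ionic-liquid-based depletion of heme and
    hemoglobin from serum and its effect on downstream immunoassays.
    Provides Soret-band (410 nm) spectrophotometric quantification via
    Beer-Lambert proportionality, the reversible first-order kinetic model of
    biphasic liquid-liquid extraction with closed-form solution and
    least-squares parameter estimation, equilibrium partition models (constant
    separation ratio and hyperbolic saturation) with depletion prediction,
    four-parameter logistic calibration and inverse prediction for competitive
    cotinine ELISA with replicate accuracy and precision statistics, Bennett
    Acceptance Ratio free-energy estimation from forward and reverse work
    samples with thermodynamic-cycle transfer free energies, a deterministic
    synthetic-data generator for every stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
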