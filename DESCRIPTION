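Package: ednaOccu
Title: Occupancy Modelling and qPCR Calibration for eDNA Monitoring of
    Vernal Pool Branchiopods
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An inference pipeline for quantitative-PCR based environmental
    DNA (eDNA) monitoring surveys of California vernal pool branchiopods.
    Takes raw qPCR well results and field sample sheets through replicate
    level detection calls with plate quality control, fits log-linear
    standard curves with limit-of-detection and limit-of-quantitation
    estimation, fits single-season site-occupancy models with imperfect
    detection (including a false-positive model for certain/uncertain
    detections), performs AIC model selection over detection covariates and
    MacKenzie-Bailey parametric-bootstrap goodness-of-fit, and converts
    fitted per-replicate detection probabilities into replicate-number
    survey-design recommendations.  A synthetic-data generator reproduces
    the full study design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'assays.R'
    'sample-sheet.R'
    'detection-history.R'
    'concordance.R'
    'qpcr.R'
    'standard-curve.R'
    'occupancy.R'
    'occu-gof.R'
    'occu-fp.R'
    'design.R'
    'simulate.R'
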