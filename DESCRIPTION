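Package: crosspk
Title: Cross-Species Pharmacokinetic Exposure Analysis for Estetrol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic (NCA) analysis and
    cross-species exposure matching for estetrol (E4). Provides a data
    model for concentration-time profiles with replicate microsampling and
    below-quantification-limit censoring; NCA parameter estimation (Cmax,
    tmax, trapezoidal AUC, terminal slope, half-life, clearance, volume of
    distribution) including biexponential curve stripping of intravenous
    bolus data by the method of residuals; closed-form simulators for
    intravenous, subcutaneous, intraperitoneal, oral (double-peak and
    secondary-reabsorption) and zero-order osmotic-minipump administration
    with log-normal assay noise; body-surface-area (Km factor) allometric
    dose translation between human and mouse; steady-state exposure
    metrics, dose-proportionality assessment, and report tables comparing
    predicted against observed interspecies exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
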