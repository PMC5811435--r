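Package: glucest
Title: Glutamate CEST MRI Simulation, Field Correction and Quantification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for glutamate chemical exchange saturation transfer
    (GluCEST) MRI analysis. Simulates pulsed-saturation z-spectrum image data
    from multi-pool Bloch-McConnell exchange models with known glutamate maps
    and smooth B0/B1 field inhomogeneity, reconstructs B0 maps from multi-echo
    gradient-echo phase and B1 maps by the double-angle method, computes
    B0/B1-corrected MTRasym (GluCEST) contrast maps, summarises ROI statistics
    and test-retest coefficients of variation, and fits the GluCEST-vs-[Glu]
    calibration line with nested-model selection to estimate the non-glutamate
    background contribution. Includes a minimal NIfTI-1 reader/writer and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
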