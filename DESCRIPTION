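Package: specalib
Title: Chemometric Calibration of Overlapping UV Spectra with PLS and
    Genetic-Algorithm Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate calibration toolkit for the simultaneous
    spectrophotometric determination of co-formulated drugs with severely
    overlapping UV absorption spectra, built around the
    favipiravir-cefixime-moxifloxacin assay. Provides a five-level,
    three-factor partial factorial mixture design, PLS1 (NIPALS) regression
    with leave-one-out cross-validation and Haaland-Thomas latent-variable
    selection, genetic-algorithm wavelength-window selection with a
    cross-validated PLS fitness, a full validation-metric battery (RMSEC,
    RMSEP, RRMSEP, BCMSEP, RMSECV, net-analyte-signal detection limits,
    recovery and method-comparison statistics), analytical eco-scale and
    GAPI greenness assessment, and a synthetic Beer-Lambert spectra
    generator for testing every stage without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
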