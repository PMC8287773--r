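Package: tfjstiff
Title: Non-Invasive Estimation of Tibiofemoral Joint Compressive Stiffness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the combined compressive stiffness (CCS) of the
    tibiofemoral joint from paired loaded/unloaded knee segmentation
    volumes. Measures the mean femur-tibia bone gap (mBGFT) per sagittal
    slice, derives the load-induced joint strain, generates
    strain-stiffness characteristics with a simplified axisymmetric
    linear-elastic frictionless-contact finite-element solver, fits the
    power-law model eps = a * E^b, and inverts it to recover a
    subject-specific effective Young's modulus for the weight-bearing
    soft tissues. Includes a synthetic knee phantom generator with known
    ground truth, a bundled six-session reference cohort, and cohort-level
    summaries with intra-subject repeatability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
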