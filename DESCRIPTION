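Package: leafgasket
Title: Leaf Area Correction for Smaller-Than-Gasket Gas Exchange Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the leaf area actually enclosed inside a circular
    gas-exchange chamber gasket when the leaf is narrower than the aperture,
    and rescales per-area gas exchange parameters accordingly. Two estimators
    are provided: a closed-form circle-segment geometry driven by a single
    caliper width measurement, and an automated image segmentation pipeline
    (scale-bar calibration, gasket-circle localisation, Otsu thresholding)
    for photographs of the leaf under a printed gasket impression. Includes
    instrument-log correction (net photosynthesis, stomatal conductance,
    transpiration, intrinsic water-use efficiency), agreement statistics
    between the two estimators, and a synthetic cereal-leaf generator with
    numerical ground-truth areas for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
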