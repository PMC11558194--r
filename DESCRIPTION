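Package: casakit
Title: Computer-Assisted Sperm Analysis for Dark-Field LED-Array Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable computer-assisted sperm analysis
    (CASA) pipeline for dark-field video from LED-array microscopes:
    a synthetic sperm-kinematics simulator and dark-field video renderer,
    threshold segmentation with an area-band particle filter, gated optimal
    frame-to-frame tracking, WHO-style motility parameters (VCL, VSL, VAP,
    LIN, STR, WOB) with 5-point path smoothing, illumination-mode
    classification for LED-array geometries, and the validation statistics
    (coefficient of variation, t-test, one-way ANOVA) used to compare
    trackers. All stages take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    tiff,
    withr,
    readr,
    generics,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
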