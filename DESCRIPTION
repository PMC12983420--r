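Package: urokin
Title: Urethral Kinematics from Transperineal Ultrasound Cine Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated quantification of urethral mobility from mid-sagittal
    transperineal ultrasound cine loops. Operator-selected regions of interest
    (proximal, mid and distal urethra, plus the pubis) are tracked through the
    loop with sparse pyramidal Lucas-Kanade optical flow and per-frame rigid
    pose estimation; segment motion is then expressed in a pubis-anchored
    anatomical coordinate system that removes probe-pubis motion. From the
    corrected pose series the package computes segmental kinematic metrics
    (displacement components, displacement vector magnitude and direction,
    rotation, urethral kink angle, relative segmental mobility), selects the
    maximum-excursion trial, and provides cohort-level summaries and
    repeated-measures statistics for group comparisons. A seeded synthetic
    speckle cine generator with known ground-truth motion supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
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
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
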