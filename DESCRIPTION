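Package: invadotrack
Title: Automated Detection and Quantification of Matrix-Degrading
    Invadopodia in Two-Channel Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments, tracks and classifies actin-rich puncta as
    matrix-degrading invadopodia from paired fluorescence time-lapse
    stacks (an intracellular actin marker channel and a labeled
    extracellular-matrix channel).  Provides photobleach, flat-field and
    translation-registration preprocessing; seed-based region-growing
    puncta segmentation with shape filters; overlap-based tracking;
    local-difference ECM degradation measurement with pre-birth baseline
    correction; one-sample t-test classification with Bonferroni
    correction; dynamic invadopodia properties (area, cell-edge distance,
    lifetime, time to maximum degradation); a parallel whole-cell
    "degrader" analysis for population-scale images with
    negative-control cutoff calibration; and a synthetic two-channel
    scene generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
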