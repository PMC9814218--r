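Package: wsitriage
Title: Weakly Supervised Triage of Prostate Core Needle Biopsy Whole Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for classifying prostate core needle biopsy
    whole slide images as benign, indolent (suitable for active surveillance)
    or aggressive (requiring definitive therapy). Implements Otsu tissue
    detection and tile grids, the 20% Gleason pattern 4/5 area-fraction
    labelling rule, a two-head tile classifier trained by weakly supervised
    hard-example mining (optionally warm-started from region annotations),
    max-probability slide aggregation with double-label handling, bootstrap
    ROC evaluation, and inter/intra-rater agreement statistics (Bennett's S,
    weighted kappa). A seeded synthetic slide generator emulates the three
    tissue texture classes so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
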