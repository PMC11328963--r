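Package: corrseg
Title: Corrective-Annotation Metrics, Region Measurement and Laser Scale
    Calibration for Benthic Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating interactively trained image-segmentation
    models on marine imagery. Computes corrective-annotation metrics
    (precision, recall, dice score, accuracy and signed area error) from
    model predictions and user corrections, rolling-mean stopping criteria
    for deciding when to end interactive training, connected-component
    region measurements (area, perimeter, equivalent diameter, eccentricity,
    centroid), pixel-to-centimetre scale calibration from paired laser dots
    or a fixed reference length, and dataset-level validation statistics
    (pooled confusion-count metrics, area-difference summaries, and
    predicted-versus-corrected area agreement). A seeded synthetic-scene
    generator with exact ground-truth bookkeeping supports testing and
    benchmarking without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
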