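Package: pfbmri
Title: Proximal Femoral Bone Classification from MRI by Geometric and
    Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of the proximal femoral bone (PFB) in 2D hip MRI
    slices, extraction of bespoke geometric, boundary-distance-curve and
    texture features, genetic-algorithm wrapper feature selection, and
    classification of bone health (healthy vs osteopenic/osteoporotic, as
    labeled by DEXA T-scores) under stratified 10-fold cross-validation.
    Includes a synthetic femur-phantom generator with controllable class
    structure so every pipeline stage can be exercised and benchmarked
    without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    rpart,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
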