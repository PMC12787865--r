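Package: trayvol
Title: Food Volume and Weight Estimation from Overhead Depth Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies served food portions from overhead tray imagery. Takes
    relative monocular depth maps and per-item segmentation masks, removes the
    perspective-induced tilt by fitting a least-squares base plane to the plate
    rim, integrates the corrected depth over each food mask into a volume in
    arbitrary units, converts volumes to weights through per-food-class density
    models, and summarises robustness of repeated passes with mean, standard
    deviation and coefficient-of-variation statistics. Includes a synthetic
    overhead-scene generator with closed-form ground-truth volumes and a
    deterministic mock perception backend for end-to-end validation without
    trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    tidyr,
    tiff,
    withr,
    EBImage,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
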