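Package: ricemoist
Title: Grain Moisture Content of Rice from Calibrated Smartphone Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures the wet-basis grain moisture content (GMC) of single
    rice panicles from RGB photographs taken on a spectral-geometric
    correction board, and projects GMC forward in time to recommend harvest
    timing. The pipeline locates the board through four corner fiducial
    markers, corrects lighting with a white/black contrast stretch and a
    gray-card gamma solve, flags specular halation, isolates grain pixels
    with a threshold cascade (excess green, hue, grayscale, stem hue),
    extracts 18 per-pixel color indices averaged per sample, selects indices
    by correlation-matrix principal component analysis, and regresses GMC
    with random forest, multilayer perceptron, support vector regression and
    multiple linear regression. Three decline models (constant daily drop,
    constant daily ratio, and a growth-day logarithmic model) forecast GMC
    over 1-8 day horizons and map it to a three-band harvest recommendation.
    A synthetic-data module renders fully ground-truthed board scenes,
    moment-matched GMC populations and multiday decline series for
    self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
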