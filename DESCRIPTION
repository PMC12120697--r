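Package: dropsizer
Title: Droplet Metrology and Print-Parameter Modelling for Microvolume Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures sessile-droplet geometry from side-view images and models
    the relationship between bioprinting parameters and dispensed droplet
    volume. The imaging pipeline converts a photograph into grayscale, edge and
    binary views, detects the droplet silhouette with a gradient-voting Hough
    circle transform, locates the substrate baseline, and computes base
    diameter, contact angle and spherical-cap volume from a pixel calibration.
    The modelling harness compares decision-tree, random-forest, polynomial,
    multilayer-perceptron and recurrent regressors of droplet volume with
    k-fold cross-validation, grid-search tuning, error metrics and normalized
    impurity-based feature importance. Seeded synthetic generators render
    droplet images with analytic ground truth and simulate parameter-to-volume
    datasets over a factorial design grid, so the full system is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
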