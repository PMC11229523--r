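Package: fruitmorph
Title: Image-Based Morphometry and Mass/Volume Estimation for
    Near-Ellipsoidal Fruits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures calibrated dimensions and projected areas of single
    near-ellipsoidal fruits (such as Rosa roxburghii) from photographs, and
    estimates fruit mass and volume from those features with a family of
    univariate and multivariate regression models.  Provides the full image
    pipeline (color adjustment, median de-pricking, gray-level de-shading,
    Canny edge detection, contour filling, HSV and K-means segmentation), a
    rotation-scan axis measurement for arbitrarily posed fruits, geometric
    (ellipsoid and paraboloid) volume approximations, a registry of published
    reference models with goodness-of-fit metrics, size grading, and a
    synthetic-fruit generator that renders test images with exact ground
    truth and samples fruit populations with realistic summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
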