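Package: colorharmony
Title: Multi-Color Feature Extraction and Color-Harmony Modeling for Real-Life Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying the color composition of raster images and
    predicting perceived color harmony. Implements circular mean filtering to
    suppress edge/semantic content, an RGB to CIELAB conversion chain (BT.709
    primaries, D65 white point), dominant-color palette construction by
    K-means clustering, watershed-by-immersion segmentation, extraction of a
    16-dimensional multi-color physical feature vector (color moments,
    grayscale entropy, space density, color-tone / lightness / warm-cool
    contrast, palette area difference), and a linear color-harmony model with
    min-max normalization, OLS fitting, k-fold cross-validated evaluation,
    threshold classification, Cronbach's alpha rater reliability, and a
    pleasure-arousal to harmony mapping. Includes synthetic fixture
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
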