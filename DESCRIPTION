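Package: chromastress
Title: Chromaticity-Difference Image Statistics and Visual Discomfort
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating the chromatic structure of images to visual
    discomfort. Implements an average local chromaticity-difference metric
    computed in the CIE 1976 (u', v') chromaticity plane, luminance-preserving
    chromatic rotations and pseudo-rotations for building matched stimulus
    triples, natural-scene corpus statistics with rectified z-scores and
    distribution-shift analysis, and linear mixed-effects inference on ordinal
    discomfort ratings with bootstrap Spearman machinery. Includes synthetic
    generators for images with controllable chromatic contrast and for
    simulated observers with known ground truth, so the full analysis chain
    can be exercised and validated without external image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    png,
    tiff,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
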