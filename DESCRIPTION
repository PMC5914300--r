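Package: dendroclean
Title: Curation of Long-Term Individual-Tree Growth Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for turning raw repeated measurements of individual trees
    from long-term forest spacing trials into complete, bias-corrected,
    monotone growth series. Implements planting-raster reconstruction from
    mapped stem positions, hypsometer triangulation of tree heights
    (including punch-card angle decoding), stem-disc based calibration of
    diameter and height measurements, isotonic regression and monotone cubic
    Hermite gap filling, penalized-spline height and crown-base smoothing
    with per-tree intercept offsets, digit-preference testing, and
    per-hectare stand summaries. A ground-truthed synthetic stand generator
    emits data in the same table schemas so that every pipeline stage can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
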