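Package: nicheshift
Title: Climatic Niche Shift Quantification Between Native and Invasive Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies climatic niche shifts of invasive species between their
    native and invaded ranges in a gridded two-axis environmental space (PCA-env).
    Builds kernel-smoothed, availability-corrected occupancy grids from occurrence
    records and gridded bioclimatic variables, measures niche overlap with
    Schoener's D, runs randomization-based niche equivalency and similarity
    tests, and computes niche expansion, stability and unfilling indices.
    Includes AICc-guided selection of climatic variables via a penalized
    occurrence-versus-background model, spatial thinning of occurrence records,
    minimum-convex-polygon backgrounds, and a synthetic-data generator that
    produces spatially autocorrelated climate-like surfaces and occurrence sets
    with known niche geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    geosphere,
    glmnet,
    ggplot2,
    jsonlite,
    rlang,
    sp,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
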