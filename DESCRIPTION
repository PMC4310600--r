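Package: rangeshift
Title: Design-Based Detection of Tree Species Range Shifts from Forest
    Inventory Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design-based survey estimation of differences between the
    distributions of tree seedlings and mature trees over plot-based
    probability samples, in the style of national forest inventories.
    Implements domain ratio estimators of the mean temperature, elevation
    and latitude of a species' occupied range, Taylor-linearized variances
    and normal confidence intervals for seedling-minus-tree differences,
    weighted empirical quantiles of range extremes with stratified
    bootstrap confidence intervals, and a generalized least squares
    combination of correlated per-species differences weighted by the
    inverse of the estimated cross-species covariance matrix. Includes a
    synthetic forest-inventory generator with known Gaussian thermal
    niches and a planted seedling shift, so every estimator can be
    validated against ground truth without confidential plot coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
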