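Package: wadihsi
Title: Habitat Suitability Index Modelling for Desert Stream (Wadi) Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits abundance-weighted Gaussian habitat-suitability curves for
    environmental parameters measured at desert stream (wadi) sites and
    combines them into a geometric-mean Habitat Suitability Index (HSI) for
    killifish (Aphaniops spp.) and similar habitat specialists. Includes a
    Cosby pedotransfer substrate-texture sub-score, quantile and preset
    suitability classification, alpha and beta diversity metrics with
    bootstrap-validated HSI-diversity correlations, a presence-background
    validation battery (confusion metrics, TSS, rank-based AUC, threshold
    selection, a normalized calibration ratio, the continuous Boyce index,
    leave-one-out cross-validation), multivariate environmental similarity
    (MESS) extrapolation analysis, ESRI ASCII grid input and output, and
    protected-area conservation gap accounting. A seeded synthetic-data
    generator emulates the sampled wadi structure so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
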