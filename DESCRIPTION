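Package: yamphen
Title: UAV-Based Shoot Biomass Estimation and Growth-Curve Analysis for
    Staked Yam
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for aerial phenotyping of
    single-staked white Guinea yam (Dioscorea rotundata). Simulates
    per-plant RGB+DEM canopy raster patches under oblique, nadir and
    combined viewing geometries; extracts projected canopy area, four
    RGB vegetation indices (GRVI, GLI, VARI and a weight-optimized
    grayscale index) and two canopy-height metrics; trains and evaluates
    support vector regression, random forest, gradient boosting and
    stepwise linear models of shoot dry weight with Shapley-value
    attributions; and fits genotype-level Richards growth curves with an
    exponential senescence term by hierarchical Bayesian MCMC, with
    split-chain convergence diagnostics and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    xgboost,
    rjags,
    coda,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
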