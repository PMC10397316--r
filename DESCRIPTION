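Package: sdmvar
Title: Species Distribution Models with Spatial and Interannual Climate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how adding sub-grid spatial variability and interannual
    temporal variability of climate to species distribution models (SDMs) changes
    predictive performance. Provides a synthetic-world generator (fine-grain
    multi-year climate cubes and virtual species with known niche archetypes),
    aggregation of fine-grain climate to coarse-grid predictor groups (means,
    spatial standard deviations, interannual variability), presence/absence
    dataset construction with geographic buffers and class-balancing weights,
    three SDM algorithms (penalized logistic regression with quadratic terms,
    thin-plate-spline GAMs, balanced-subsample random forests), repeated
    split-sample evaluation with TSS and AUC, and mixed-model plus geographic
    comparison of predictor groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
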