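Package: sdmflow
Title: Bias-Aware Species Distribution Modelling Pipeline with
    Ensemble Habitat Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for correlative species
    distribution modelling of wide-ranging species from presence-only
    records. Covers occurrence cleaning and covariate collinearity
    screening, sampling-effort density surfaces, Ripley's L and Moran's I
    spatial-structure diagnostics with resolution scanning, replicate
    spatial thinning, random and effort-weighted pseudo-absence
    generation, three model families (quadratic logistic GLM, boosted
    regression trees, and a maximum-entropy-style penalized logistic on
    an expanded feature basis), two-phase AICc candidate-model selection,
    cross-validation and leave-one-region-out transferability evaluation
    with AUC and Kappa at the max(sensitivity+specificity) threshold,
    model-specific covariate importance, and Kappa-weighted ensemble
    habitat-suitability maps. Ships a virtual-species landscape simulator
    with known truth so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    spatial,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
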