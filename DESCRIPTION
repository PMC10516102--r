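Package: ensembleSDM
Title: Ensemble Species Distribution Modelling with Range-Change and
    Protected-Area Effectiveness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for ensemble species distribution
    modelling under present and future climate scenarios: principal
    component reduction of bioclimatic predictors, occurrence thinning,
    environmentally restricted pseudo-absence sampling, spatially
    structured (checkerboard) and random k-fold cross-validation, five
    suitability algorithms (GLM, penalized-logistic MaxEnt analogue,
    random forest, support vector machine, Gaussian process), an
    above-mean ensemble with max-Jaccard binarization, land-cover
    masking, range-change and richness accounting, and two
    protected-area effectiveness assessments (per-species gap analysis
    with log-interpolated representation targets, and a
    shape-preserving randomization null model for richness). Includes a
    synthetic-landscape and virtual-species generator so the whole
    pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    randomForest,
    e1071,
    kernlab
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
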