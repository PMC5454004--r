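Package: fxscreen
Title: Linguistic and Cognitive Computational Phenotyping for Fragile X
    Premutation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated screening framework for Fragile X (FX) premutation
    carrier status from five-minute language samples and executive-function
    scores. Parses one-utterance-per-line transcripts with optional
    SALT-style maze annotations, extracts an 88-feature linguistic profile
    (dysfluencies, complexity, density, five-segment decomposition),
    combines it with a 15-feature BRIEF-A-style cognitive block, ranks
    features by information gain with MDL-stopped supervised
    discretization, and evaluates five classifiers under stratified 10-fold
    cross-validation with natively implemented confusion-matrix metrics,
    ROC/AUC, Matthews correlation and population-screening positive
    predictive value. Includes a seeded two-group synthetic cohort
    generator with controllable dysfluency and cognitive effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
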