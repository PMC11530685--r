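Package: raindropRF
Title: Weighted Random Forest Feature Selection with a Raindrop Metaheuristic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the effect of exercise programmes on physical-fitness
    indicators with a modified random forest: information-gain splits, per-node
    Gini importance bookkeeping, out-of-bag weighted tree voting,
    noise-perturbation importance, and iterative percentage-based feature
    elimination. Forest hyperparameters can be tuned either by grid search with
    k-fold cross-validation or by an opposition-based-learning artificial
    raindrop optimizer with a fixed-capacity elite pool, adaptive flow
    coefficient, and stagnation escape. Includes a synthetic fitness-data
    generator with planted informative indicators, missing cells and 3-sigma
    outliers, an end-to-end evaluation pipeline (mean imputation, outlier
    removal, stratified splits, classification metrics, top-k precision against
    planted ground truth), and an optimizer benchmark harness on the Ackley and
    Rastrigin test functions against differential-evolution and
    particle-swarm baselines.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
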