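Package: mediboost
Title: Interpretable Decision Trees via Boosting with Soft Membership
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows single, clinician-readable decision trees that inherit the
    accuracy of boosted stump ensembles. An ensemble of decision stumps can be
    rewritten as a tree in which every root-to-leaf path replays the ensemble;
    this package grows such trees directly, specialising each branch through a
    per-instance membership function whose decay is controlled by an
    acceleration parameter. Two induction engines are provided: an
    exponential-loss (AdaBoost-style) variant and a binomial log-likelihood
    gradient-boosting variant with ridge-regularised Newton leaf coefficients.
    Includes impossible-path elimination, sign-preserving pruning, mean/mode
    imputation with missingness indicators, stratified repeated and nested
    cross-validation with balanced error and AUC, label-permutation testing, a
    model-comparison harness, seeded synthetic-data generators, Graphviz DOT
    and rule-list export, and a JSON model format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
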