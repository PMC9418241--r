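Package: bnnclassify
Title: Uncertainty-Aware Cancer Type Classification with Bayesian Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class classification of cancer types and subtypes from
    bulk gene-expression profiles using a mean-field variational Bayesian
    neural network trained by Bayes by Backprop. Monte-Carlo sampling of the
    weight posterior yields per-sample epistemic uncertainty estimates that
    can be used either to filter out unreliable predictions or to correct
    predicted probabilities through a per-class ordinary-least-squares model
    on the logit scale. Includes PCA-loading feature selection with a
    logistic-regression plateau rule, a single-gene classification screen,
    deterministic stratified splitting and cross-validation folds, a
    synthetic multi-class expression-cohort generator with a closed-form
    Bayes-error oracle, confusion-matrix metrics, and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    generics,
    glmnet,
    nnet,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
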