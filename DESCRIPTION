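Package: drcfit
Title: Doubly Robust Estimation of Average Causal Effects with Cross-Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the average causal effect of a binary exposure on a
    continuous outcome using the doubly robust estimators AIPW (augmented
    inverse probability weighting) and TMLE (targeted maximum likelihood
    estimation), with nuisance models fitted by a from-scratch Super Learner
    ensemble and optional K-fold cross-fitting. Includes a suite of synthetic
    data-generating mechanisms emulating the confounding structure of an
    early-life birth-cohort study (mixed binary/continuous confounders with
    sequential dependence, simple and complex exposure/outcome models, small
    and large confounder sets), calibration of the exposure effect to a target
    rejection power, empirical computation of the true effect, and Monte Carlo
    performance evaluation (bias, empirical and model-based standard errors,
    coverage, power, with Monte Carlo standard errors) including a stability
    exclusion rule for extreme replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    glmnet,
    mgcv,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
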