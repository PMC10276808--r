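Package: svycausal
Title: Survey-Weighted Matching and Weighting Methods for Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for incorporating complex survey weights and design into
    matching- and weighting-based causal inference: propensity score matching
    with original or inherited survey weights, coarsened exact matching with
    survey-weight binning, inverse probability of treatment weighting and
    weighting by the odds, all estimated by pseudo-likelihood generalized
    linear models with design-based Taylor-linearization variance for
    stratified cluster samples. Includes a finite-population simulator with a
    stratified two-stage sampling stage, potential-outcome truth computation,
    and a Monte-Carlo replicate driver producing bias and confidence-interval
    coverage tables, plus sensitivity analyses for unmeasured confounding and
    exposure/outcome prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
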