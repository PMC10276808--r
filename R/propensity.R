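# Propensity score estimation (two ways of incorporating the survey
# weights), propensity-based analysis weights (IPTW and weighting by the
# odds), and covariate balance diagnostics.

#' Estimate propensity scores in a survey sample
#'
#' Two modes of bringing the survey weights into the logistic propensity
#' model `logit(e_i) = b0 + b1 X_1 + ... + bp X_p`:
#' `"osw_weighted"` fits the model by OSW-weighted logistic regression;
#' `"osw_covariate"` fits an unweighted logistic regression with the OSW
#' appended as an additional covariate. Fitted probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` (positivity guard; the number of clipped values is
#' recorded).
#'
#' @param data A data frame.
#' @param covariates Character vector of covariate column names.
#' @param mode `"osw_covariate"` or `"osw_weighted"`.
#' @param exposure Binary exposure column name.
#' @param weight_col Survey-weight (OSW) column name.
#' @return An object of class `svc_propensity`: list with `e_hat`, `mode`,
#'   `fit` (the underlying [svy_glm()]), and `n_clipped`.
#' @export
estimate_propensity <- function(data, covariates,
                                mode = c("osw_covariate", "osw_weighted"),
                                exposure = "insomnia", weight_col = "weight") {
  mode <- match.arg(mode)
  stopifnot(length(covariates) >= 1, all(covariates %in% names(data)))
  if (is.null(data[[weight_col]])) {
    stop("survey-weight column `", weight_col, "` not found", call. = FALSE)
  }
  if (mode == "osw_covariate") {
    form <- stats::reformulate(c(covariates, weight_col), response = exposure)
    fit <- svy_glm(data, form, family = "binomial")
  } else {
    form <- stats::reformulate(covariates, response = exposure)
    fit <- svy_glm(data, form, family = "binomial", weights = weight_col)
  }
  e_raw <- fit$fitted
  e_hat <- pmin(1 - 1e-6, pmax(1e-6, e_raw))
  structure(list(e_hat = e_hat, mode = mode, fit = fit,
                 n_clipped = sum(e_raw != e_hat)),
            class = "svc_propensity")
}

#' Propensity-based analysis weights
#'
#' Inverse probability of treatment weights
#' `w_i = Z_i / e_i + (1 - Z_i) / (1 - e_i)` target the ATE; odds weights
#' `w_i = Z_i + (1 - Z_i) e_i / (1 - e_i)` keep the exposed at weight 1 and
#' weight the unexposed by their odds of exposure, targeting the ATT.
#'
#' @param e_hat Propensity scores in (0, 1).
#' @param z Binary exposure indicator.
#' @param kind `"iptw"` or `"odds"`.
#' @return Numeric weights.
#' @export
propensity_weights <- function(e_hat, z, kind = c("iptw", "odds")) {
  kind <- match.arg(kind)
  if (inherits(e_hat, "svc_propensity")) e_hat <- e_hat$e_hat
  stopifnot(all(e_hat > 0 & e_hat < 1), all(z %in% c(0, 1)))
  if (kind == "iptw") {
    z / e_hat + (1 - z) / (1 - e_hat)
  } else {
    z + (1 - z) * e_hat / (1 - e_hat)
  }
}

#' Absolute standardized mean differences before and after adjustment
#'
#' The absolute SMD of a covariate is
#' `|mean_exposed - mean_unexposed| / s_exposed`, where the group means use
#' the analysis-stage weights and the denominator is always the OSW-weighted
#' standard deviation of the covariate in the *full* exposed group, before
#' any matching or pruning. Categorical covariates contribute one SMD per
#' level, using level proportions as means.
#'
#' @param data The full sample (pre-matching).
#' @param covariates Covariate column names.
#' @param exposure Binary exposure column name.
#' @param weight_col OSW column name (used for the "before" columns and for
#'   the denominator).
#' @param rows Row indices of the analysis (matched/weighted) subset;
#'   default all rows.
#' @param analysis_weights Analysis weights aligned with `rows` (e.g. OSW,
#'   ISW, CEMW or products); default the OSW of `rows`.
#' @return A tibble with columns `covariate`, `level` (NA for numeric),
#'   `smd_before`, `smd_after`. Zero-variance denominators yield `NaN` with
#'   a warning.
#' @export
balance_table <- function(data, covariates, exposure = "insomnia",
                          weight_col = "weight", rows = NULL,
                          analysis_weights = NULL) {
  z <- data[[exposure]]
  osw <- data[[weight_col]] %||% rep(1, nrow(data))
  if (is.null(rows)) rows <- seq_len(nrow(data))
  if (is.null(analysis_weights)) analysis_weights <- osw[rows]
  stopifnot(length(analysis_weights) == length(rows))

  one <- function(x, lvl = NA_character_) {
    s_exp <- sqrt(weighted_var(x[z == 1], osw[z == 1]))
    if (s_exp == 0) {
      warning("zero exposed-group SD; SMD undefined", call. = FALSE)
    }
    before <- abs(weighted_mean(x[z == 1], osw[z == 1]) -
                    weighted_mean(x[z == 0], osw[z == 0])) / s_exp
    xa <- x[rows]; za <- z[rows]
    after <- abs(weighted_mean(xa[za == 1], analysis_weights[za == 1]) -
                   weighted_mean(xa[za == 0], analysis_weights[za == 0])) / s_exp
    tibble::tibble(level = lvl, smd_before = before, smd_after = after)
  }

  purrr::map_dfr(covariates, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      dplyr::mutate(one(x), covariate = v, .before = 1)
    } else {
      purrr::map_dfr(sort(unique(as.character(x))), function(l) {
        dplyr::mutate(one(as.numeric(as.character(x) == l), l),
                      covariate = v, .before = 1)
      })
    }
  })
}
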