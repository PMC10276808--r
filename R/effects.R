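# Causal effect estimation for one survey sample under one method
# configuration: PSM / CEM / IPTW / odds weighting, with the various
# survey-weight schemes, estimated by pseudo-likelihood GLM with
# design-based variance whenever analysis weights are in play.

.scheme_by_family <- list(
  psm = c("none", "osw", "isw"),
  cem = c("cemw", "cemw_osw"),
  iptw = c("psw", "psw_osw"),
  odds = c("psw", "psw_osw")
)

#' Specify one method configuration
#'
#' @param family `"psm"`, `"cem"`, `"iptw"` or `"odds"`.
#' @param ps_mode Propensity estimation mode (`"osw_covariate"` or
#'   `"osw_weighted"`); ignored for CEM.
#' @param cem_bin_osw For CEM: also bin on the coarsened survey weight?
#' @param adjusted Adjust the outcome model for the covariates (conditional
#'   estimand) or not (marginal estimand)?
#' @param scheme Analysis-weight scheme, compatible with the family: PSM
#'   `"none"`/`"osw"`/`"isw"`; CEM `"cemw"`/`"cemw_osw"`; weighting
#'   `"psw"`/`"psw_osw"`.
#' @param specification `"correct"` (confounder included in all models) or
#'   `"under"` (confounder omitted everywhere).
#' @param outcome `"mci"` (prevalent; odds ratios) or `"htn"` (incident
#'   hypertension; rate ratios with a log-years offset).
#' @param scenario Sampling scenario the configuration applies to (1 or 2).
#' @return A one-row tibble of class `svc_method_config`.
#' @export
method_config <- function(family = c("psm", "cem", "iptw", "odds"),
                          ps_mode = c("osw_covariate", "osw_weighted"),
                          cem_bin_osw = FALSE,
                          adjusted = FALSE,
                          scheme = NULL,
                          specification = c("correct", "under"),
                          outcome = c("mci", "htn"),
                          scenario = 1L) {
  family <- match.arg(family)
  ps_mode <- match.arg(ps_mode)
  specification <- match.arg(specification)
  outcome <- match.arg(outcome)
  if (is.null(scheme)) scheme <- .scheme_by_family[[family]][1]
  if (!scheme %in% .scheme_by_family[[family]]) {
    stop("scheme `", scheme, "` is not valid for family `", family, "`",
         call. = FALSE)
  }
  stopifnot(scenario %in% c(1L, 2L))
  out <- tibble::tibble(
    family = family,
    ps_mode = if (family == "cem") NA_character_ else ps_mode,
    cem_bin_osw = if (family == "cem") cem_bin_osw else NA,
    adjusted = adjusted, scheme = scheme, specification = specification,
    outcome = outcome, scenario = as.integer(scenario)
  )
  class(out) <- c("svc_method_config", class(out))
  out
}

#' Full grid of method configurations
#'
#' Every combination studied in the simulation: PSM with both propensity
#' modes and weight schemes none/OSW/ISW; CEM with and without binning on
#' the coarsened survey weight, weighted by CEMW or CEMW x OSW; IPTW and
#' odds weighting with PSW or PSW x OSW; each unadjusted and adjusted.
#'
#' @param outcomes,scenarios,specifications Values to cross the grid with.
#' @return A tibble of configurations, one per row.
#' @export
method_grid <- function(outcomes = "mci", scenarios = 1L,
                        specifications = "correct") {
  base <- dplyr::bind_rows(
    tidyr::expand_grid(family = "psm",
                       ps_mode = c("osw_weighted", "osw_covariate"),
                       cem_bin_osw = NA, adjusted = c(FALSE, TRUE),
                       scheme = c("none", "osw", "isw")),
    tidyr::expand_grid(family = "cem", ps_mode = NA_character_,
                       cem_bin_osw = c(FALSE, TRUE), adjusted = c(FALSE, TRUE),
                       scheme = c("cemw", "cemw_osw")),
    tidyr::expand_grid(family = c("iptw", "odds"),
                       ps_mode = c("osw_weighted", "osw_covariate"),
                       cem_bin_osw = NA, adjusted = c(FALSE, TRUE),
                       scheme = c("psw", "psw_osw"))
  )
  out <- tidyr::expand_grid(
    tibble::tibble(outcome = outcomes),
    tibble::tibble(scenario = as.integer(scenarios)),
    tibble::tibble(specification = specifications),
    base
  )
  dplyr::relocate(out, "family", "ps_mode", "cem_bin_osw", "adjusted",
                  "scheme", "specification", "outcome", "scenario")
}

# Estimand targeted by a configuration: IPTW targets
# the ATE/CATE; PSM, CEM and odds weighting target the ATT/CATT.
config_estimand <- function(config) {
  marginal <- if (config$family == "iptw") "ate" else "att"
  conditional <- if (config$family == "iptw") "cate" else "catt"
  if (config$adjusted) conditional else marginal
}

#' Estimate a causal effect in one survey sample
#'
#' Runs one method configuration end to end: restricts to individuals
#' without observed baseline hypertension for the incident-hypertension
#' outcome (before propensity estimation and matching), estimates the
#' propensity score or CEM bins, builds the analysis weights for the
#' requested scheme (products taken element-wise), and fits the outcome
#' model -- logistic for prevalent MCI, Poisson-log with a log-years offset
#' for incident hypertension -- with design-based standard errors whenever
#' analysis weights are used, model-based otherwise.
#'
#' @param sample A survey sample from [draw_survey_sample()] (or a table
#'   from [read_analysis_table()] with the same canonical columns).
#' @param config A one-row configuration from [method_config()] or a row of
#'   [method_grid()].
#' @param confounder Name of the measured confounder used (with BMI) in the
#'   propensity/binning and adjusted outcome models; defaults to the
#'   sample's `confounder` attribute (age, or education in the education
#'   sensitivity mode).
#' @return A one-row tibble: the configuration columns, `estimand`,
#'   `scale` (`"OR"` or `"IRR"`), `estimate` (exponentiated exposure
#'   coefficient), `conf.low`, `conf.high`, `log_se` and `n_used`.
#' @export
estimate_causal_effect <- function(sample, config, confounder = NULL) {
  stopifnot(nrow(config) == 1)
  confounder <- confounder %||% attr(sample, "confounder") %||% "age"
  covs <- c("bmi", if (config$specification == "correct") confounder)

  if (config$outcome == "htn") {
    sample <- sample[sample$htn_v1 == 0, , drop = FALSE]
  }
  z <- sample$insomnia
  if (!any(z == 1) || !any(z == 0)) {
    stop("exposure group empty after restriction", call. = FALSE)
  }

  rows <- seq_len(nrow(sample))
  a_wt <- NULL   # NULL = unweighted analysis, model-based variance
  if (config$family %in% c("psm", "iptw", "odds")) {
    ps <- estimate_propensity(sample, covs, mode = config$ps_mode)
    if (config$family == "psm") {
      m <- psm_match(sample, ps)
      rows <- attr(m, "matched_rows")
      a_wt <- switch(config$scheme,
        none = NULL,
        osw = sample$weight[rows],
        isw = assign_isw(m, sample)
      )
    } else {
      psw <- propensity_weights(ps, z, kind = config$family)
      a_wt <- switch(config$scheme,
        psw = psw,
        psw_osw = psw * sample$weight
      )
    }
  } else {
    plan_vars <- c(covs,
                   if (config$outcome == "htn") "years_between",
                   if (isTRUE(config$cem_bin_osw)) "weight")
    plan <- cem_default_plan(sample, plan_vars)
    cem <- cem_match(sample, plan)
    rows <- cem$row
    a_wt <- switch(config$scheme,
      cemw = cem$cemw,
      cemw_osw = cem$cemw * sample$weight[rows]
    )
  }

  dat <- sample[rows, , drop = FALSE]
  design <- if (is.null(a_wt)) NULL else svy_design("stratum", "bg_id")
  terms <- c("insomnia", if (config$adjusted) covs)
  if (config$outcome == "mci") {
    fit <- svy_glm(dat, stats::reformulate(terms, "mci"),
                   family = "binomial", weights = a_wt, design = design)
    scale <- "OR"
  } else {
    fit <- svy_glm(dat, stats::reformulate(terms, "htn_v2"),
                   family = "poisson", weights = a_wt,
                   offset = log(dat$years_between), design = design)
    scale <- "IRR"
  }
  ci <- wald_interval(fit, "insomnia", exponentiate = TRUE)
  dplyr::bind_cols(
    config,
    tibble::tibble(
      estimand = config_estimand(config), scale = scale,
      estimate = exp(fit$coefficients[["insomnia"]]),
      conf.low = unname(ci[1]), conf.high = unname(ci[2]),
      log_se = fit$se[["insomnia"]], n_used = nrow(dat)
    )
  )
}
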