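# True causal effects of the finite population, computed from the doubled
# potential-outcome frame: one row per (individual, exposure level), so the
# marginal and conditional estimands can be read off ordinary (unweighted
# maximum-likelihood) regressions -- the frame *is* the target population.

#' Expand a population to its doubled potential-outcome frame
#'
#' @param population A frame from [generate_population()] carrying the six
#'   potential-outcome columns.
#' @return A tibble with `2N` rows: each individual appears once with
#'   `a = 0` (carrying its `Y(0)` outcomes) and once with `a = 1`.
#' @export
expand_to_potential_frame <- function(population) {
  need <- c("mci_pot0", "mci_pot1", "htn_v1_pot0", "htn_v1_pot1",
            "htn_v2_pot0", "htn_v2_pot1")
  if (!all(need %in% names(population))) {
    stop("population lacks potential-outcome columns", call. = FALSE)
  }
  base <- population[c("person_id", "bmi", "age", "years_between", "insomnia",
                       intersect("education", names(population)))]
  a0 <- dplyr::mutate(base, a = 0L,
                      mci = population$mci_pot0,
                      htn_v1 = population$htn_v1_pot0,
                      htn_v2 = population$htn_v2_pot0)
  a1 <- dplyr::mutate(base, a = 1L,
                      mci = population$mci_pot1,
                      htn_v1 = population$htn_v1_pot1,
                      htn_v2 = population$htn_v2_pot1)
  out <- dplyr::bind_rows(a0, a1)
  attr(out, "confounder") <- attr(population, "confounder") %||% "age"
  out
}

# Marginal logistic MLE of y on binary a via the aggregated 2x2 counts
# (identical to the full-frame fit, instantly).
marginal_logistic_or <- function(a, y) {
  p1 <- mean(y[a == 1]); p0 <- mean(y[a == 0])
  if (any(c(p1, p0) %in% c(0, 1))) {
    stop("degenerate outcome table in truth computation", call. = FALSE)
  }
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

# Marginal Poisson-log MLE of y on binary a with offset log(t): the ratio
# of event rates per unit exposure time.
marginal_poisson_irr <- function(a, y, t) {
  r1 <- sum(y[a == 1]) / sum(t[a == 1])
  r0 <- sum(y[a == 0]) / sum(t[a == 0])
  if (r0 == 0 || r1 == 0) stop("degenerate rate in truth computation",
                               call. = FALSE)
  r1 / r0
}

conditional_fit <- function(df, response, family, conf, offset = NULL) {
  X <- cbind(1, a = df$a, bmi = df$bmi, conf = df[[conf]])
  fam <- if (family == "binomial") stats::quasibinomial() else stats::quasipoisson()
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = df[[response]], family = fam,
    offset = offset %||% rep(0, nrow(X)),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("truth regression did not converge", call. = FALSE)
  exp(fit$coefficients[["a"]])
}

#' True causal effects from the doubled potential-outcome frame
#'
#' For prevalent MCI, logistic regressions of the potential outcome on the
#' exposure level `a` give the marginal (ATE/ATT) and, adding BMI and the
#' confounder, conditional (CATE/CATT) odds ratios. For incident
#' hypertension, Poisson log-link regressions with a log-years offset give
#' rate ratios, restricted to frame rows without hypertension at baseline
#' under the same exposure level (`baseline_exclusion = "potential"`, the
#' default) or without observed baseline hypertension
#' (`baseline_exclusion = "observed"`). ATT/CATT use only the rows of
#' individuals observed as exposed. All fits are ordinary unweighted ML:
#' the doubled frame is the whole target population, so no survey design
#' applies.
#'
#' @param population A frame from [generate_population()], or a
#'   potential-outcome frame from [expand_to_potential_frame()].
#' @param baseline_exclusion How to exclude baseline hypertension in the
#'   incident-hypertension truth: per potential row or by observed status.
#' @return A tibble of class `svc_true_effects` with columns `outcome`
#'   (`"mci"`, `"htn"`), `estimand` (`"ate"`, `"att"`, `"cate"`, `"catt"`),
#'   `scale` and `estimate` (ratio scale).
#' @export
true_effects <- function(population,
                         baseline_exclusion = c("potential", "observed")) {
  baseline_exclusion <- match.arg(baseline_exclusion)
  pf <- if ("a" %in% names(population)) population
        else expand_to_potential_frame(population)
  conf <- attr(pf, "confounder") %||% "age"

  res <- list()
  for (sub in c("all", "exposed")) {
    d <- if (sub == "exposed") pf[pf$insomnia == 1, ] else pf
    marg <- if (sub == "all") "ate" else "att"
    cond <- if (sub == "all") "cate" else "catt"
    res[[length(res) + 1]] <- tibble::tibble(
      outcome = "mci", estimand = c(marg, cond), scale = "OR",
      estimate = c(marginal_logistic_or(d$a, d$mci),
                   conditional_fit(d, "mci", "binomial", conf))
    )
    dh <- if (baseline_exclusion == "potential") d[d$htn_v1 == 0, ]
          else d[(d$a == 1 & d$htn_v1 == 0) | (d$a == 0 & d$htn_v1 == 0), ]
    if (baseline_exclusion == "observed") {
      obs_free <- d$person_id %in%
        d$person_id[d$a == d$insomnia & d$htn_v1 == 0]
      dh <- d[obs_free, ]
    }
    res[[length(res) + 1]] <- tibble::tibble(
      outcome = "htn", estimand = c(marg, cond), scale = "IRR",
      estimate = c(marginal_poisson_irr(dh$a, dh$htn_v2, dh$years_between),
                   conditional_fit(dh, "htn_v2", "poisson", conf,
                                   offset = log(dh$years_between)))
    )
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("svc_true_effects", class(out))
  out
}

lookup_true_effect <- function(true_eff, outcome, estimand) {
  v <- true_eff$estimate[true_eff$outcome == outcome &
                           true_eff$estimand == estimand]
  if (length(v) != 1) stop("true effect not found for ", outcome, "/",
                           estimand, call. = FALSE)
  v
}
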