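# Finite-population generator: covariates, household/block-group random
# effects, insomnia exposure, and potential outcomes (prevalent MCI at visit
# 2; hypertension at visits 1 and 2) under logistic data-generating models.

# Default uneven split of the 752 block groups across 8 strata, frozen once
# from a seeded multinomial so the design is fixed and reproducible.
.default_stratum_sizes <- c(92L, 91L, 105L, 92L, 81L, 91L, 104L, 96L)

#' Configuration of the simulated finite population
#'
#' Describes the target population: 752 census block groups (BGs) split
#' unevenly across 8 strata, a varying number of two-person households (HHs)
#' per BG, covariate distributions (age, BMI, years between visits),
#' household and BG random intercepts, and logistic models for the insomnia
#' exposure and for the three binary outcomes. All coefficient defaults are
#' the log odds ratios of the data-generating models; see the package
#' vignette for the full model statements.
#'
#' @param n_bg Number of block groups.
#' @param n_strata Number of sampling strata.
#' @param stratum_sizes Integer vector (length `n_strata`) of BG counts per
#'   stratum, summing to `n_bg`. Default: a fixed uneven split of 752.
#' @param hh_per_bg_mean Mean of the exponential distribution of HH counts
#'   per BG (rounded to an integer with floor 1).
#' @param persons_per_hh Household size; the sampling design assumes 2.
#' @param hh_mean_age,bmi,years Lists `list(mean, sd, lo, hi)` giving the
#'   truncated-normal distributions of the HH mean age, BMI (kg/m^2), and
#'   years between visits.
#' @param age_halfwidth Individual ages are drawn uniformly on the integers
#'   within this many years of the HH mean age.
#' @param hh_re_sd,bg_re_sd Standard deviations of the household and BG
#'   random intercepts shared by all outcome models.
#' @param exposure_coefs Named vector `(intercept, bmi, confounder)` of the
#'   logistic exposure model, on the log-odds scale.
#' @param mci_coefs,htn1_coefs Named vectors
#'   `(intercept, exposure, bmi, confounder)` of the logistic models for
#'   prevalent MCI at visit 2 and hypertension at visit 1.
#' @param htn2_coefs Named vector
#'   `(intercept, exposure, bmi, confounder, years)` for hypertension at
#'   visit 2.
#' @param confounder_mode `"age"` (default) or `"education"`. In education
#'   mode a new variable correlated with age replaces age in all four
#'   association models; age is still generated and still drives the
#'   scenario-1 sampling design.
#' @param education_rho Target correlation between education and age
#'   (required in education mode), one of the values typically studied:
#'   0.25, 0.5, 0.75.
#' @return A validated list of class `svc_pop_config`.
#' @export
pop_config <- function(n_bg = 752L,
                       n_strata = 8L,
                       stratum_sizes = NULL,
                       hh_per_bg_mean = 450,
                       persons_per_hh = 2L,
                       hh_mean_age = list(mean = 40, sd = 15, lo = 23, hi = 69),
                       age_halfwidth = 10,
                       bmi = list(mean = 29, sd = 9, lo = 15, hi = 63),
                       years = list(mean = 6, sd = 0.5, lo = 3, hi = 9),
                       hh_re_sd = 1,
                       bg_re_sd = 0.5,
                       exposure_coefs = c(intercept = log(0.109),
                                          bmi = log(1.025),
                                          confounder = log(1.019)),
                       mci_coefs = c(intercept = log(0.003),
                                     exposure = log(1.560),
                                     bmi = log(1.018),
                                     confounder = log(1.056)),
                       htn1_coefs = c(intercept = log(0.002),
                                      exposure = log(1.065),
                                      bmi = log(1.088),
                                      confounder = log(1.082)),
                       htn2_coefs = c(intercept = log(0.001),
                                      exposure = log(1.247),
                                      bmi = log(1.082),
                                      confounder = log(1.092),
                                      years = log(1.098)),
                       confounder_mode = c("age", "education"),
                       education_rho = NULL) {
  confounder_mode <- match.arg(confounder_mode)
  n_bg <- as.integer(n_bg)
  n_strata <- as.integer(n_strata)
  stopifnot(n_bg >= n_strata, n_strata >= 1, hh_per_bg_mean > 0,
            hh_re_sd >= 0, bg_re_sd >= 0, age_halfwidth >= 0)
  if (as.integer(persons_per_hh) != 2L) {
    stop("the two-stage design assumes households of exactly 2 individuals",
         call. = FALSE)
  }
  if (is.null(stratum_sizes)) {
    if (n_bg == 752L && n_strata == 8L) {
      stratum_sizes <- .default_stratum_sizes
    } else {
      # scale the default shape to the requested population size
      base <- rep_len(.default_stratum_sizes, n_strata)
      stratum_sizes <- pmax(1L, as.integer(round(base / sum(base) * n_bg)))
      gap <- n_bg - sum(stratum_sizes)
      stratum_sizes[seq_len(abs(gap))] <-
        stratum_sizes[seq_len(abs(gap))] + sign(gap)
    }
  }
  stratum_sizes <- as.integer(stratum_sizes)
  if (length(stratum_sizes) != n_strata || any(stratum_sizes < 1) ||
      sum(stratum_sizes) != n_bg) {
    stop("`stratum_sizes` must have length `n_strata`, be positive, and sum to `n_bg`",
         call. = FALSE)
  }
  for (d in list(hh_mean_age, bmi, years)) {
    stopifnot(is.list(d), all(c("mean", "sd", "lo", "hi") %in% names(d)),
              d$sd > 0, d$lo < d$hi)
  }
  check_coefs <- function(x, nms) {
    if (!is.numeric(x) || !all(nms %in% names(x)) || any(!is.finite(x))) {
      stop("coefficient vector must be finite and named ",
           paste(nms, collapse = ", "), call. = FALSE)
    }
    x[nms]
  }
  exposure_coefs <- check_coefs(exposure_coefs, c("intercept", "bmi", "confounder"))
  mci_coefs <- check_coefs(mci_coefs, c("intercept", "exposure", "bmi", "confounder"))
  htn1_coefs <- check_coefs(htn1_coefs, c("intercept", "exposure", "bmi", "confounder"))
  htn2_coefs <- check_coefs(htn2_coefs,
                            c("intercept", "exposure", "bmi", "confounder", "years"))
  if (confounder_mode == "education") {
    if (is.null(education_rho) || education_rho <= 0 || education_rho >= 1) {
      stop("education mode requires `education_rho` in (0, 1)", call. = FALSE)
    }
  }
  structure(
    list(n_bg = n_bg, n_strata = n_strata, stratum_sizes = stratum_sizes,
         hh_per_bg_mean = hh_per_bg_mean, persons_per_hh = 2L,
         hh_mean_age = hh_mean_age, age_halfwidth = age_halfwidth,
         bmi = bmi, years = years, hh_re_sd = hh_re_sd, bg_re_sd = bg_re_sd,
         exposure_coefs = exposure_coefs, mci_coefs = mci_coefs,
         htn1_coefs = htn1_coefs, htn2_coefs = htn2_coefs,
         confounder_mode = confounder_mode, education_rho = education_rho),
    class = "svc_pop_config"
  )
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling of the normal distribution conditioned on
#' `[lo, hi]`, so the bounds are never atoms (no clipping spikes).
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal; `sd > 0`.
#' @param lo,hi Truncation interval, `lo < hi`.
#' @return `n` values in `[lo, hi]`.
#' @export
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (!all(is.finite(c(mean, sd, lo, hi))) || sd <= 0 || lo >= hi) {
    stop("`rtruncnorm` needs finite parameters with sd > 0 and lo < hi",
         call. = FALSE)
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

# Linear predictors of the four association models. `conf` is the value of
# whichever variable plays the confounder role (age, or education in the
# education sensitivity mode).
exposure_lp <- function(bmi, conf, coefs) {
  coefs[["intercept"]] + coefs[["bmi"]] * bmi + coefs[["confounder"]] * conf
}

outcome_lp <- function(a, bmi, conf, h, b, coefs, years = NULL) {
  lp <- coefs[["intercept"]] + coefs[["exposure"]] * a + coefs[["bmi"]] * bmi +
    coefs[["confounder"]] * conf + h + b
  if (!is.null(years)) lp <- lp + coefs[["years"]] * years
  lp
}

# Covariate / random-effect skeleton of the population (everything upstream
# of the exposure and outcome draws), rows ordered BG, HH, person with the
# two HH members on adjacent rows.
generate_structure <- function(config, seed) {
  with_substream(seed, "hh_counts", {
    hh_per_bg <- pmax(1L, as.integer(round(stats::rexp(config$n_bg,
                                                       1 / config$hh_per_bg_mean))))
  })
  n_hh <- sum(hh_per_bg)
  n <- 2L * n_hh
  stratum_of_bg <- rep.int(seq_len(config$n_strata), config$stratum_sizes)
  bg_of_hh <- rep.int(seq_len(config$n_bg), hh_per_bg)

  d <- config$hh_mean_age
  with_substream(seed, "hh_mean_age", {
    hh_mean_age <- rtruncnorm(n_hh, d$mean, d$sd, d$lo, d$hi)
  })
  lo <- ceiling(hh_mean_age - config$age_halfwidth)
  hi <- floor(hh_mean_age + config$age_halfwidth)
  with_substream(seed, "ages", {
    age1 <- lo + floor(stats::runif(n_hh) * (hi - lo + 1))
    age2 <- lo + floor(stats::runif(n_hh) * (hi - lo + 1))
  })
  with_substream(seed, "bmi", {
    bmi <- rtruncnorm(n, config$bmi$mean, config$bmi$sd,
                      config$bmi$lo, config$bmi$hi)
  })
  with_substream(seed, "years", {
    years <- rtruncnorm(n, config$years$mean, config$years$sd,
                        config$years$lo, config$years$hi)
  })
  with_substream(seed, "hh_effect", {
    h_hh <- stats::rnorm(n_hh, 0, config$hh_re_sd)
  })
  with_substream(seed, "bg_effect", {
    b_bg <- stats::rnorm(config$n_bg, 0, config$bg_re_sd)
  })

  pop <- tibble::tibble(
    bg_id = rep(bg_of_hh, each = 2L),
    stratum = stratum_of_bg[rep(bg_of_hh, each = 2L)],
    hh_id = rep(seq_len(n_hh), each = 2L),
    person_id = seq_len(n),
    age = as.numeric(rbind(age1, age2)),
    bmi = bmi,
    years_between = years,
    hh_effect = rep(h_hh, each = 2L),
    bg_effect = b_bg[rep(bg_of_hh, each = 2L)]
  )
  if (config$confounder_mode == "education") {
    edu <- with_substream(seed, "education", {
      generate_education(pop$age, config$education_rho)
    })
    pop$education <- edu$education
    attr(pop, "education_q") <- edu$q
  }
  pop
}

confounder_values <- function(pop, config) {
  if (config$confounder_mode == "education") pop$education else pop$age
}

add_exposure <- function(pop, config, seed) {
  conf <- confounder_values(pop, config)
  pop$p_insomnia <- expit(exposure_lp(pop$bmi, conf, config$exposure_coefs))
  with_substream(seed, "exposure", {
    pop$insomnia <- as.integer(stats::runif(nrow(pop)) < pop$p_insomnia)
  })
  pop
}

add_outcomes <- function(pop, config, seed) {
  conf <- confounder_values(pop, config)
  draw <- function(lp, u) as.integer(u < expit(lp))
  n <- nrow(pop)
  with_substream(seed, "outcomes", {
    u_mci <- matrix(stats::runif(2 * n), n)
    u_h1 <- matrix(stats::runif(2 * n), n)
    u_h2 <- matrix(stats::runif(2 * n), n)
  })
  with_ <- function(coefs, a, years = NULL) {
    outcome_lp(a, pop$bmi, conf, pop$hh_effect, pop$bg_effect, coefs, years)
  }
  pop$mci_pot0 <- draw(with_(config$mci_coefs, 0), u_mci[, 1])
  pop$mci_pot1 <- draw(with_(config$mci_coefs, 1), u_mci[, 2])
  pop$htn_v1_pot0 <- draw(with_(config$htn1_coefs, 0), u_h1[, 1])
  pop$htn_v1_pot1 <- draw(with_(config$htn1_coefs, 1), u_h1[, 2])
  pop$htn_v2_pot0 <- draw(with_(config$htn2_coefs, 0, pop$years_between), u_h2[, 1])
  pop$htn_v2_pot1 <- draw(with_(config$htn2_coefs, 1, pop$years_between), u_h2[, 2])
  z <- pop$insomnia
  pop$mci <- z * pop$mci_pot1 + (1L - z) * pop$mci_pot0
  pop$htn_v1 <- z * pop$htn_v1_pot1 + (1L - z) * pop$htn_v1_pot0
  pop$htn_v2 <- z * pop$htn_v2_pot1 + (1L - z) * pop$htn_v2_pot0
  pop
}

#' Generate the finite target population
#'
#' Builds one finite population under the data-generating models in
#' [pop_config()]: HH counts per BG are exponential (rounded, floor 1); a HH
#' mean age is drawn from a truncated normal and the two members' integer
#' ages uniformly within `age_halfwidth` years of it; BMI and years between
#' visits are independent truncated normals; the insomnia exposure follows
#' its logistic model; and each binary outcome is drawn under both exposure
#' levels (potential outcomes) from logistic models that share household and
#' BG random intercepts. Observed outcomes are selected by the realized
#' exposure.
#'
#' @param config A [pop_config()].
#' @param seed Integer seed; every variable family uses its own named
#'   substream, so the same seed reproduces the frame exactly.
#' @return A tibble with one row per individual: design labels (`bg_id`,
#'   `stratum`, `hh_id`, `person_id`), covariates, random effects,
#'   `p_insomnia`, `insomnia`, the six potential outcomes
#'   (`*_pot0`, `*_pot1`), and observed `mci`, `htn_v1`, `htn_v2`.
#'   Attributes `config`, `seed` and `confounder` record provenance.
#' @export
#' @examples
#' pop <- generate_population(pop_config(n_bg = 16, hh_per_bg_mean = 8), seed = 1)
#' mean(pop$insomnia)
generate_population <- function(config = pop_config(), seed = 1L) {
  stopifnot(inherits(config, "svc_pop_config"))
  pop <- generate_structure(config, seed)
  pop <- add_exposure(pop, config, seed)
  pop <- add_outcomes(pop, config, seed)
  attr(pop, "config") <- config
  attr(pop, "seed") <- seed
  attr(pop, "confounder") <- config$confounder_mode
  pop
}

#' Generate an education variable with a target correlation with age
#'
#' Each value starts as a uniform draw on `[min(age), max(age)]` and is
#' replaced by the individual's own age with probability `q`, where `q` is
#' solved numerically from the mixture moment identities
#' `Cov(E, A) = q Var(A)` and
#' `Var(E) = q E[A^2] + (1 - q) E[U^2] - (q E[A] + (1 - q) E[U])^2`
#' so that `cor(E, A)` equals `rho`.
#'
#' @param ages Numeric vector of ages.
#' @param rho Target correlation in (0, 1).
#' @return A list with `education` (values) and `q` (the replacement
#'   probability used).
#' @export
generate_education <- function(ages, rho) {
  stopifnot(length(ages) > 1, rho > 0, rho < 1)
  va <- stats::var(ages)
  if (va <= 0) stop("education calibration failed: ages have zero variance",
                    call. = FALSE)
  mn <- min(ages); mx <- max(ages)
  ea <- mean(ages); eu <- (mn + mx) / 2
  vu <- (mx - mn)^2 / 12
  rho_of_q <- function(q) {
    ve <- q * (va + ea^2) + (1 - q) * (vu + eu^2) - (q * ea + (1 - q) * eu)^2
    q * va / sqrt(va * ve)
  }
  q <- stats::uniroot(function(q) rho_of_q(q) - rho,
                      interval = c(1e-10, 1 - 1e-10), tol = 1e-10)$root
  u <- stats::runif(length(ages), mn, mx)
  replace <- stats::runif(length(ages)) < q
  list(education = ifelse(replace, ages, u), q = q)
}

#' Calibrate model intercepts to target prevalences
#'
#' Adjusts the intercepts of the exposure and/or outcome models so that the
#' expected population prevalence (the mean of the model probabilities over
#' the generated covariates and random effects) matches each target. The
#' expected prevalence is strictly increasing in the intercept, so a
#' root-finding search converges; the exposure is recalibrated first because
#' the observed outcome prevalences depend on the realized exposure.
#'
#' @param config A [pop_config()].
#' @param targets Named list with any of `exposure`, `mci`, `htn1`, `htn2`,
#'   each a target prevalence in (0, 1).
#' @param seed Seed used to generate the calibration population.
#' @param tol Acceptable absolute difference between achieved and target
#'   prevalence (default 0.005, i.e. half a percentage point).
#' @return A list with `config` (intercepts replaced), `achieved` (named
#'   expected prevalences) and `intercepts`.
#' @export
calibrate_intercepts <- function(config, targets, seed = 1L, tol = 0.005) {
  stopifnot(inherits(config, "svc_pop_config"), is.list(targets))
  bad <- setdiff(names(targets), c("exposure", "mci", "htn1", "htn2"))
  if (length(bad)) stop("unknown calibration targets: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (t in targets) stopifnot(t > 0, t < 1)

  pop <- generate_structure(config, seed)
  conf <- confounder_values(pop, config)
  achieved <- c()

  solve_intercept <- function(lp_minus_intercept, target) {
    f <- function(i0) mean(expit(i0 + lp_minus_intercept)) - target
    if (f(-40) > 0 || f(20) < 0) {
      stop("calibration failure: target prevalence ", target,
           " is not achievable", call. = FALSE)
    }
    stats::uniroot(f, c(-40, 20), tol = 1e-9)$root
  }

  if (!is.null(targets$exposure)) {
    base <- exposure_lp(pop$bmi, conf, config$exposure_coefs) -
      config$exposure_coefs[["intercept"]]
    i0 <- solve_intercept(base, targets$exposure)
    config$exposure_coefs[["intercept"]] <- i0
    achieved["exposure"] <- mean(expit(i0 + base))
  }
  pop <- add_exposure(pop, config, seed)
  z <- pop$insomnia

  recal_outcome <- function(coefs, target, years = NULL) {
    base <- outcome_lp(z, pop$bmi, conf, pop$hh_effect, pop$bg_effect,
                       coefs, years) - coefs[["intercept"]]
    i0 <- solve_intercept(base, target)
    coefs[["intercept"]] <- i0
    list(coefs = coefs, achieved = mean(expit(i0 + base)))
  }
  if (!is.null(targets$mci)) {
    r <- recal_outcome(config$mci_coefs, targets$mci)
    config$mci_coefs <- r$coefs; achieved["mci"] <- r$achieved
  }
  if (!is.null(targets$htn1)) {
    r <- recal_outcome(config$htn1_coefs, targets$htn1)
    config$htn1_coefs <- r$coefs; achieved["htn1"] <- r$achieved
  }
  if (!is.null(targets$htn2)) {
    r <- recal_outcome(config$htn2_coefs, targets$htn2, pop$years_between)
    config$htn2_coefs <- r$coefs; achieved["htn2"] <- r$achieved
  }
  for (nm in names(achieved)) {
    if (abs(achieved[[nm]] - targets[[nm]]) > tol) {
      stop("calibration failure for ", nm, call. = FALSE)
    }
  }
  list(config = config, achieved = achieved,
       intercepts = c(exposure = config$exposure_coefs[["intercept"]],
                      mci = config$mci_coefs[["intercept"]],
                      htn1 = config$htn1_coefs[["intercept"]],
                      htn2 = config$htn2_coefs[["intercept"]]))
}
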