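# Monte-Carlo replicate driver: draws repeated survey samples from one
# fixed population, runs every method configuration on each, and aggregates
# bias and 95%-CI coverage against the population true effects.

#' The four robust matching configurations
#'
#' The matching approaches that keep nominal coverage even when a
#' design-related confounder is omitted: PSM with the survey weight as a
#' propensity covariate and OSW-weighted estimation, and CEM binning on the
#' coarsened survey weight with CEMW x OSW estimation -- each unadjusted
#' and adjusted.
#'
#' @inheritParams method_grid
#' @return A tibble of configurations.
#' @export
robust_configs <- function(outcomes = "mci", scenarios = 1L,
                           specifications = "correct") {
  g <- method_grid(outcomes, scenarios, specifications)
  dplyr::filter(
    g,
    (.data$family == "psm" & .data$ps_mode == "osw_covariate" &
       .data$scheme == "osw") |
      (.data$family == "cem" & .data$cem_bin_osw & .data$scheme == "cemw_osw")
  )
}

#' Run replicate survey samples and aggregate bias and coverage
#'
#' Computes the true effects once for the population, then for each of
#' `n_reps` replicates draws one survey sample per scenario appearing in
#' `configs` and evaluates every configuration on it. Bias is the mean of
#' `estimate - TE` on the ratio scale; coverage is the fraction of
#' replicates whose exponentiated 95% Wald interval contains `TE`.
#' Replicate-level failures (non-convergence, empty matched sets) are
#' caught, logged and excluded; a configuration failing in more than 10% of
#' replicates is flagged invalid.
#'
#' @param population A frame from [generate_population()].
#' @param configs Configurations, e.g. [method_grid()] or
#'   [robust_configs()].
#' @param n_reps Number of replicate samples (>= 2).
#' @param seed Integer seed; replicate `r` uses an independent substream,
#'   so results do not depend on evaluation order.
#' @param true_eff Optional precomputed [true_effects()] table.
#' @param verbose Print a progress message every 50 replicates.
#' @return A tibble of class `svc_metrics`: one row per configuration with
#'   `bias`, `cover`, `mc_se_bias`, `mc_se_cover`, `mean_estimate`,
#'   `true_effect`, `n_reps_used`, `n_fail`, `valid`. The per-replicate
#'   estimates are kept in `attr(, "replicates")`.
#' @export
run_replicates <- function(population, configs, n_reps, seed = 1L,
                           true_eff = NULL, verbose = FALSE) {
  stopifnot(n_reps >= 2, nrow(configs) >= 1)
  if (is.null(true_eff)) true_eff <- true_effects(population)
  scenarios <- unique(configs$scenario)
  confounder <- attr(population, "confounder") %||% "age"

  rows <- vector("list", n_reps * nrow(configs))
  k <- 0L
  for (r in seq_len(n_reps)) {
    for (sc in scenarios) {
      smp <- draw_survey_sample(population, scenario = sc,
                                seed = substream_seed(seed, paste0("rep", r)))
      sub <- configs[configs$scenario == sc, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        cfg <- sub[i, , drop = FALSE]
        est <- tryCatch(
          suppressWarnings(
            estimate_causal_effect(smp, cfg, confounder = confounder)),
          error = function(e) {
            dplyr::bind_cols(cfg, tibble::tibble(
              estimand = config_estimand(cfg), scale = NA_character_,
              estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
              log_se = NA_real_, n_used = NA_integer_))
          })
        est$rep <- r
        k <- k + 1L
        rows[[k]] <- est
      }
    }
    if (verbose && r %% 50 == 0) {
      message("replicate ", r, "/", n_reps)
    }
  }
  reps <- dplyr::bind_rows(rows[seq_len(k)])
  out <- aggregate_metrics(reps, true_eff)
  attr(out, "replicates") <- reps
  attr(out, "true_effects") <- true_eff
  attr(out, "seed") <- seed
  out
}

# Aggregate per-replicate estimates into the bias / coverage table.
aggregate_metrics <- function(reps, true_eff) {
  keys <- c("family", "ps_mode", "cem_bin_osw", "adjusted", "scheme",
            "specification", "outcome", "scenario", "estimand")
  out <- reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      te <- lookup_true_effect(true_eff, g$outcome, g$estimand)
      ok <- !is.na(d$estimate)
      n <- sum(ok)
      covered <- d$conf.low[ok] <= te & te <= d$conf.high[ok]
      tibble::tibble(
        true_effect = te,
        bias = mean(d$estimate[ok] - te),
        cover = mean(covered),
        mc_se_bias = stats::sd(d$estimate[ok]) / sqrt(n),
        mc_se_cover = sqrt(mean(covered) * (1 - mean(covered)) / n),
        mean_estimate = mean(d$estimate[ok]),
        n_reps_used = n,
        n_fail = sum(!ok)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(valid = .data$n_fail <= 0.1 * (.data$n_reps_used + .data$n_fail))
  class(out) <- c("svc_metrics", class(out))
  out
}

#' Flag methods that are robust across scenarios and specifications
#'
#' A method (identified by family, propensity mode / binning, adjustment
#' and weight scheme, per outcome) is flagged robust when its coverage lies
#' in the closed band `[0.93, 0.97]` in three cells: scenario 1 and 2 under
#' correct specification, and scenario 1 under under-specification. Methods
#' missing any of those cells get `NA`.
#'
#' @param metrics A [run_replicates()] metrics table covering the needed
#'   cells.
#' @param band Closed coverage band, default `c(0.93, 0.97)`.
#' @return A tibble with the method keys and a logical `robust` column.
#' @export
classify_robust <- function(metrics, band = c(0.93, 0.97)) {
  need <- list(c(1L, "correct"), c(2L, "correct"), c(1L, "under"))
  keys <- c("family", "ps_mode", "cem_bin_osw", "adjusted", "scheme", "outcome")
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      in_band <- vapply(need, function(cell) {
        row <- d[d$scenario == as.integer(cell[1]) &
                   d$specification == cell[2], ]
        if (nrow(row) != 1) return(NA)
        row$cover >= band[1] & row$cover <= band[2]
      }, logical(1))
      tibble::tibble(robust = if (anyNA(in_band)) NA else all(in_band))
    }) |>
    dplyr::ungroup()
}

#' Sensitivity analyses of the simulation study
#'
#' Three designs:
#' `"unmeasured_confounder"` re-runs the configurations with the confounder
#' omitted everywhere (`specification = "under"`) in both sampling
#' scenarios. `"education_correlation"` generates populations in education
#' mode for each correlation in `rho_values` and runs the robust methods
#' under correct and under-specification (scenario 1). `"prevalence_grid"`
#' recalibrates the exposure and outcome model intercepts to each prevalence
#' in `prevalences` and runs the robust methods (scenario 1, correct
#' specification).
#'
#' @param which Which sensitivity analysis to run.
#' @param base_config The baseline [pop_config()].
#' @param n_reps,seed Replicates and seed, as in [run_replicates()].
#' @param configs Configurations to evaluate; defaults to the four robust
#'   methods ([robust_configs()]) for the appropriate cells.
#' @param outcomes Outcomes to study.
#' @param rho_values Education-age correlations to scan.
#' @param prevalences Exposure/outcome prevalence grid values (proportions).
#' @param verbose Passed to [run_replicates()].
#' @return A metrics tibble; education results gain a `rho` column,
#'   prevalence results gain `prev_exposure` and `prev_outcome`.
#' @export
run_sensitivity <- function(which = c("unmeasured_confounder",
                                      "education_correlation",
                                      "prevalence_grid"),
                            base_config = pop_config(), n_reps = 100,
                            seed = 1L, configs = NULL, outcomes = "mci",
                            rho_values = c(0.25, 0.5, 0.75),
                            prevalences = c(0.05, 0.15, 0.25, 0.35),
                            verbose = FALSE) {
  which <- match.arg(which)
  if (which == "unmeasured_confounder") {
    if (is.null(configs)) {
      configs <- method_grid(outcomes, scenarios = c(1L, 2L),
                             specifications = "under")
    }
    pop <- generate_population(base_config, seed = substream_seed(seed, "pop"))
    return(run_replicates(pop, configs, n_reps, seed, verbose = verbose))
  }

  if (which == "education_correlation") {
    res <- purrr::map(rho_values, function(rho) {
      cfg <- base_config
      cfg$confounder_mode <- "education"
      cfg$education_rho <- rho
      pop <- generate_population(cfg, seed = substream_seed(seed, "pop"))
      if (is.null(configs)) {
        configs <- robust_configs(outcomes, scenarios = 1L,
                                  specifications = c("correct", "under"))
      }
      m <- run_replicates(pop, configs, n_reps,
                          seed = substream_seed(seed, paste0("rho", rho)),
                          verbose = verbose)
      dplyr::mutate(m, rho = rho, .before = 1)
    })
    out <- dplyr::bind_rows(res)
    class(out) <- c("svc_metrics", class(out))
    return(out)
  }

  # prevalence grid: exposure prevalence x outcome prevalence
  grid <- tidyr::expand_grid(prev_exposure = prevalences,
                             prev_outcome = prevalences)
  res <- purrr::pmap(grid, function(prev_exposure, prev_outcome) {
    targets <- list(exposure = prev_exposure)
    if ("mci" %in% outcomes) targets$mci <- prev_outcome
    if ("htn" %in% outcomes) {
      targets$htn1 <- prev_outcome
      targets$htn2 <- prev_outcome
    }
    cal <- calibrate_intercepts(base_config, targets,
                                seed = substream_seed(seed, "pop"))
    pop <- generate_population(cal$config, seed = substream_seed(seed, "pop"))
    cfg <- configs %||% robust_configs(outcomes, scenarios = 1L,
                                       specifications = "correct")
    m <- run_replicates(pop, cfg, n_reps,
                        seed = substream_seed(seed,
                                              paste(prev_exposure, prev_outcome)),
                        verbose = verbose)
    dplyr::mutate(m, prev_exposure = prev_exposure,
                  prev_outcome = prev_outcome, .before = 1)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("svc_metrics", class(out))
  out
}
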