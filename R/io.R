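# Configuration files, CSV/JSON serialization, fixtures, and the generic
# real-data adapter for externally supplied survey analysis tables.

.run_config_keys <- c("population", "n_reps", "seed", "scenarios",
                      "outcomes", "specifications", "out_dir")
.pop_config_keys <- c("n_bg", "n_strata", "stratum_sizes", "hh_per_bg_mean",
                      "persons_per_hh", "hh_mean_age", "age_halfwidth",
                      "bmi", "years", "hh_re_sd", "bg_re_sd",
                      "exposure_coefs", "mci_coefs", "htn1_coefs",
                      "htn2_coefs", "confounder_mode", "education_rho")

#' Load a run configuration from a JSON file
#'
#' Unknown keys are rejected by name; missing keys are filled with the
#' package defaults (an empty file yields the full default configuration).
#' The `population` entry accepts any [pop_config()] argument; named
#' coefficient vectors are given as JSON objects.
#'
#' @param path Path to a JSON file.
#' @return A list of class `svc_run_config` with elements `population`
#'   (a [pop_config()]), `n_reps`, `seed`, `scenarios`, `outcomes`,
#'   `specifications`, `out_dir`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) raw <- list()
  bad <- setdiff(names(raw), .run_config_keys)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pop_args <- raw$population %||% list()
  bad <- setdiff(names(pop_args), .pop_config_keys)
  if (length(bad)) {
    stop("unknown population keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("exposure_coefs", "mci_coefs", "htn1_coefs", "htn2_coefs")) {
    if (!is.null(pop_args[[nm]])) pop_args[[nm]] <- unlist(pop_args[[nm]])
  }
  for (nm in c("hh_mean_age", "bmi", "years")) {
    if (!is.null(pop_args[[nm]])) pop_args[[nm]] <- as.list(pop_args[[nm]])
  }
  n_reps <- raw$n_reps %||% 1000L
  if (n_reps < 2) stop("`n_reps` must be at least 2", call. = FALSE)
  seed <- raw$seed %||% 1L
  structure(list(
    population = do.call(pop_config, pop_args),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    scenarios = as.integer(raw$scenarios %||% 1L),
    outcomes = raw$outcomes %||% "mci",
    specifications = raw$specifications %||% "correct",
    out_dir = raw$out_dir %||% "."
  ), class = "svc_run_config")
}

#' Write a run configuration to JSON
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config An `svc_run_config` (or a list of overrides).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  pop <- config$population
  payload <- list(
    population = list(
      n_bg = pop$n_bg, n_strata = pop$n_strata,
      stratum_sizes = pop$stratum_sizes,
      hh_per_bg_mean = pop$hh_per_bg_mean,
      hh_mean_age = pop$hh_mean_age, age_halfwidth = pop$age_halfwidth,
      bmi = pop$bmi, years = pop$years,
      hh_re_sd = pop$hh_re_sd, bg_re_sd = pop$bg_re_sd,
      exposure_coefs = as.list(pop$exposure_coefs),
      mci_coefs = as.list(pop$mci_coefs),
      htn1_coefs = as.list(pop$htn1_coefs),
      htn2_coefs = as.list(pop$htn2_coefs),
      confounder_mode = pop$confounder_mode,
      education_rho = pop$education_rho
    ),
    n_reps = config$n_reps, seed = config$seed,
    scenarios = config$scenarios, outcomes = config$outcomes,
    specifications = config$specifications, out_dir = config$out_dir
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Deterministic miniature data sets for examples and tests
#'
#' @param kind `"population"`, `"sample"`, `"matched"` or `"bins"`.
#' @param seed Integer seed.
#' @return A small object of the requested kind (about 200 rows or fewer
#'   for the population), exercising every column of the full-scale
#'   counterpart; `"bins"` is constructed so at least one bin is pruned.
#' @export
make_fixture <- function(kind = c("population", "sample", "matched", "bins"),
                         seed = 42L) {
  kind <- match.arg(kind)
  cfg <- pop_config(n_bg = 16L, n_strata = 8L, hh_per_bg_mean = 6)
  pop <- generate_population(cfg, seed = seed)
  if (kind == "population") return(pop)
  smp <- draw_survey_sample(pop, scenario = 1L, seed = seed,
                            bg_prob = rep(0.9, 8), hh_prob = 0.8)
  if (kind == "sample") return(smp)
  if (kind == "matched") {
    ps <- estimate_propensity(smp, c("bmi", "age"))
    return(psm_match(smp, ps))
  }
  # bins: coarse age bins on a small sample leave some bins one-sided
  cem_match(smp, list(age = stats::quantile(smp$age, c(0.1, 0.3, 0.5, 0.7, 0.9),
                                            names = FALSE),
                      bmi = c(18.5, 25, 30)))
}

#' Read a generic survey analysis table
#'
#' Adapts an externally supplied flat CSV (one row per individual) to the
#' canonical columns the estimation functions use: `stratum`, `bg_id`
#' (PSU), `weight`, `insomnia` (exposure) and outcome/covariate columns.
#' Weights must be strictly positive; the exposure must be binary after
#' optional recoding. Rows with missing values in mapped columns are
#' dropped (complete-case analysis) with a message.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping canonical names to
#'   file columns, e.g.
#'   `c(stratum = "strat", psu = "BGid", weight = "WEIGHT_FINAL",
#'      exposure = "insomnia", mci = "mci")`. Entries other than
#'   `stratum`, `psu`, `weight`, `exposure` are carried over under their
#'   canonical names.
#' @param exposure_recode Optional named vector recoding exposure values,
#'   e.g. `c(yes = 1, no = 0)`.
#' @return A tibble with canonical columns, ready for
#'   [estimate_causal_effect()].
#' @export
read_analysis_table <- function(path, column_map,
                                exposure_recode = NULL) {
  need <- c("stratum", "psu", "weight", "exposure")
  if (!all(need %in% names(column_map))) {
    stop("`column_map` must name columns for ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[unname(column_map)])
  canonical <- names(column_map)
  canonical[canonical == "psu"] <- "bg_id"
  canonical[canonical == "exposure"] <- "insomnia"
  names(out) <- canonical

  cc <- stats::complete.cases(out)
  if (any(!cc)) {
    message(sum(!cc), " row(s) dropped for missing values")
    out <- out[cc, , drop = FALSE]
  }
  if (!is.null(exposure_recode)) {
    out$insomnia <- unname(exposure_recode[as.character(out$insomnia)])
  }
  if (!all(out$insomnia %in% c(0, 1))) {
    stop("exposure is not binary after recoding", call. = FALSE)
  }
  bad_w <- which(!(out$weight > 0))
  if (length(bad_w)) {
    stop("nonpositive weight at row(s): ",
         paste(utils::head(bad_w, 5), collapse = ", "), call. = FALSE)
  }
  out$insomnia <- as.integer(out$insomnia)
  attr(out, "confounder") <- "age"
  out
}

#' Write a tidy metrics or population table to CSV
#'
#' @param x A tibble (metrics table, population, sample, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
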