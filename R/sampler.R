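# Stratified two-stage survey sampling from the finite population, with
# base weights (inverse inclusion probabilities) and normalized final
# weights (OSW).

#' Household inclusion probability from the oldest member's age
#'
#' In the primary design (scenario 1) the household sampling probability is
#' `expit(-8 + 0.1 * max_hh_age)`, so households with older members are
#' oversampled.
#'
#' @param max_hh_age Maximum age in the household.
#' @return Inclusion probability in (0, 1).
#' @export
hh_inclusion_probability <- function(max_hh_age) {
  stopifnot(all(is.finite(max_hh_age)))
  expit(-8 + 0.1 * max_hh_age)
}

#' Draw a stratified two-stage survey sample
#'
#' Stage 1 keeps each block group independently with its stratum-specific
#' probability (default 25% in strata 1-4 and 60% in strata 5-8). Stage 2
#' keeps each household in a retained BG independently: in scenario 1 with
#' [hh_inclusion_probability()] of the oldest member's age, in scenario 2
#' with a constant age-free probability equal to the population mean of the
#' scenario-1 probabilities (so the two scenarios have matching expected
#' sample sizes and differ only in age-dependence). Both members of a kept
#' household enter the sample.
#'
#' Per-stage inclusion probabilities are attached (`p_bg`, `p_hh`,
#' `p_ind = p_bg * p_hh`), base weights are `1 / p_ind`, and the final
#' weights `weight` (the original survey weights, OSW) are the base weights
#' divided by their sample mean, so they average exactly 1.
#'
#' @param population A population frame from [generate_population()].
#' @param scenario 1 (age-dependent household sampling) or 2 (age-free).
#' @param seed Integer seed for the sampling draws.
#' @param bg_prob Optional numeric vector of per-stratum BG sampling
#'   probabilities (length `n_strata`); defaults to 0.25 for the first half
#'   of the strata and 0.60 for the rest.
#' @param hh_prob Optional override of the household inclusion
#'   probabilities: a single number or a function of the HH maximum age.
#'   Intended for design experiments; the scenarios above are the defaults.
#' @return A tibble of sampled individuals with all population columns plus
#'   `p_bg`, `p_hh`, `p_ind`, `base_weight`, `weight`. Attributes `scenario`
#'   and `confounder` are carried along.
#' @export
draw_survey_sample <- function(population, scenario = 1L, seed = 1L,
                               bg_prob = NULL, hh_prob = NULL) {
  stopifnot(scenario %in% c(1L, 2L))
  stratum_of_bg <- population$stratum[!duplicated(population$bg_id)]
  n_bg <- length(stratum_of_bg)
  n_strata <- max(stratum_of_bg)
  if (is.null(bg_prob)) {
    bg_prob <- ifelse(seq_len(n_strata) <= ceiling(n_strata / 2), 0.25, 0.60)
  }
  stopifnot(length(bg_prob) == n_strata, all(bg_prob > 0), all(bg_prob <= 1))

  # household-level view: the two members of a HH occupy adjacent rows
  n <- nrow(population)
  i1 <- seq.int(1L, n, by = 2L)
  max_age <- pmax(population$age[i1], population$age[i1 + 1L])
  bg_of_hh <- population$bg_id[i1]

  if (is.null(hh_prob)) {
    p_hh <- hh_inclusion_probability(max_age)
    if (scenario == 2L) p_hh <- rep(mean(p_hh), length(p_hh))
  } else if (is.function(hh_prob)) {
    p_hh <- rep_len(hh_prob(max_age), length(max_age))
  } else {
    p_hh <- rep_len(hh_prob, length(max_age))
  }
  stopifnot(all(p_hh > 0), all(p_hh <= 1))
  p_bg_of_bg <- bg_prob[stratum_of_bg]

  with_substream(seed, "sample", {
    keep_bg <- stats::runif(n_bg) < p_bg_of_bg
    keep_hh <- keep_bg[bg_of_hh] & (stats::runif(length(p_hh)) < p_hh)
  })
  if (!any(keep_hh)) {
    stop("empty survey sample: no household was selected", call. = FALSE)
  }

  keep_row <- rep(keep_hh, each = 2L)
  smp <- population[keep_row, , drop = FALSE]
  smp$p_bg <- rep(p_bg_of_bg[bg_of_hh][keep_hh], each = 2L)
  smp$p_hh <- rep(p_hh[keep_hh], each = 2L)
  smp$p_ind <- smp$p_bg * smp$p_hh
  smp$base_weight <- 1 / smp$p_ind
  smp$weight <- normalize_weights(smp$base_weight)
  attr(smp, "scenario") <- as.integer(scenario)
  attr(smp, "confounder") <- attr(population, "confounder") %||% "age"
  attr(smp, "seed") <- seed
  smp
}

#' Normalize base weights to mean one
#'
#' @param w Positive base weights.
#' @return `w / mean(w)`, the final analysis weights (OSW).
#' @export
normalize_weights <- function(w) {
  stopifnot(all(w > 0))
  w / mean(w)
}
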