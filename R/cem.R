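# Coarsened exact matching: coarsen continuous variables into bins,
# cross-classify, prune bins lacking either exposure group, and construct
# CEM weights that re-balance each bin's composition to the exposed group.

#' Coarsen a continuous variable into half-open bins
#'
#' Cutpoints are interior boundaries: values fall into
#' `(-Inf, c1), [c1, c2), ..., [cK, Inf)`, so a value exactly at a cutpoint
#' belongs to the right-hand bin, and values below or above the cutpoint
#' range land in the first or last bin.
#'
#' @param x Numeric vector.
#' @param cutpoints Strictly increasing numeric cutpoints.
#' @return Integer bin ids in `1..(length(cutpoints) + 1)` with a
#'   `"labels"` attribute of interval labels.
#' @export
coarsen <- function(x, cutpoints) {
  if (length(cutpoints) == 0) {
    stop("`cutpoints` must be a nonempty increasing vector", call. = FALSE)
  }
  stopifnot(!is.unsorted(cutpoints, strictly = TRUE), all(is.finite(cutpoints)))
  bins <- findInterval(x, cutpoints) + 1L
  bounds <- c(-Inf, cutpoints, Inf)
  labels <- paste0("[", bounds[-length(bounds)], ",", bounds[-1], ")")
  attr(bins, "labels") <- labels
  bins
}

#' Default coarsening plan for the simulated covariates
#'
#' BMI uses the clinical bins 18.5 / 25 / 30; the confounder (age or
#' education), years between visits, and (optionally) the survey weights
#' use within-sample quantiles, mirroring the convention of using
#' meaningful cutpoints when available and quantiles otherwise.
#'
#' @param data Sample the quantile cutpoints are computed from.
#' @param variables Variables to coarsen.
#' @param weight_col Survey-weight column (quintile cutpoints) when
#'   `"weight"` is included.
#' @return Named list of cutpoint vectors, usable as `plan` in
#'   [cem_match()].
#' @export
cem_default_plan <- function(data, variables, weight_col = "weight") {
  qs <- function(x, p) unique(stats::quantile(x, p, names = FALSE))
  plan <- list()
  for (v in variables) {
    plan[[v]] <- if (v == "bmi") {
      c(18.5, 25, 30)
    } else if (v == weight_col) {
      qs(data[[v]], c(0.2, 0.4, 0.6, 0.8))
    } else {
      qs(data[[v]], c(0.25, 0.5, 0.75))
    }
  }
  plan
}

#' Coarsened exact matching with CEM weights
#'
#' Individuals are cross-classified by the coarsened matching variables
#' (optionally including the coarsened survey weight). Bins without at
#' least one exposed and one unexposed individual are pruned. Retained
#' exposed individuals get weight 1; retained unexposed individuals in bin
#' `b` get
#' `(n_unexposed / n_exposed) * (n_{b,exposed} / n_{b,unexposed})`,
#' where the totals are over the retained (matched) sample, so the weighted
#' unexposed composition of every bin equals the exposed composition.
#'
#' @param data A data frame.
#' @param plan Named list of cutpoint vectors, e.g. from
#'   [cem_default_plan()]; names are the matching variables.
#' @param exposure Binary exposure column name.
#' @return A tibble of class `svc_cem` with columns `row` (row index into
#'   `data`), `bin` and `cemw`; attribute `pruned_rows` lists the discarded
#'   row indices.
#' @export
cem_match <- function(data, plan, exposure = "insomnia") {
  stopifnot(is.list(plan), length(plan) > 0, !is.null(names(plan)))
  z <- data[[exposure]]
  stopifnot(all(z %in% c(0, 1)))
  bin_ids <- lapply(names(plan), function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("matching variable `", v, "` not found", call. = FALSE)
    coarsen(x, plan[[v]])
  })
  bin <- do.call(paste, c(bin_ids, sep = "."))

  n1_b <- tapply(z, bin, sum)
  n_b <- tapply(z, bin, length)
  n0_b <- n_b - n1_b
  keep_bins <- names(n_b)[n1_b >= 1 & n0_b >= 1]
  if (length(keep_bins) == 0) {
    stop("all bins were pruned: no overlap between exposure groups",
         call. = FALSE)
  }
  keep <- bin %in% keep_bins
  n1 <- sum(z[keep])
  n0 <- sum(keep) - n1
  ratio <- (n0 / n1) * (n1_b[bin[keep]] / n0_b[bin[keep]])
  cemw <- ifelse(z[keep] == 1, 1, as.numeric(ratio))

  out <- tibble::tibble(row = which(keep), bin = bin[keep], cemw = cemw)
  attr(out, "pruned_rows") <- which(!keep)
  class(out) <- c("svc_cem", class(out))
  out
}
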