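# ggplot2 displays for metrics tables and balance diagnostics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

method_label <- function(d) {
  paste0(toupper(d$family),
         ifelse(!is.na(d$ps_mode) & d$ps_mode == "osw_covariate", "/OSWcov",
                ifelse(!is.na(d$ps_mode), "/OSWwt", "")),
         ifelse(!is.na(d$cem_bin_osw) & d$cem_bin_osw, "/binOSW", ""),
         ifelse(d$adjusted, "/adj", "/unadj"),
         "/", d$scheme)
}

#' Plot bias and coverage of a metrics table
#'
#' One panel per performance measure; methods on the vertical axis, points
#' colored by weight scheme, faceted by scenario and specification. The
#' dashed guides mark zero bias and the 0.93-0.97 coverage band.
#'
#' @param object A metrics table from [run_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svc_metrics
#' @export
autoplot.svc_metrics <- function(object, ...) {
  d <- dplyr::mutate(object, method = method_label(object))
  long <- tidyr::pivot_longer(d, c("bias", "cover"),
                              names_to = "measure", values_to = "value")
  guides <- tibble::tibble(measure = c("bias", "cover", "cover"),
                           value = c(0, 0.93, 0.97))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$method,
                                     color = .data$scheme)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = guides,
                        ggplot2::aes(xintercept = .data$value),
                        linetype = "dashed", color = "grey50") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$scenario, .data$specification),
      cols = ggplot2::vars(.data$measure), scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, color = "weights") +
    ggplot2::theme_minimal()
}

#' Love plot of covariate balance
#'
#' Absolute standardized mean differences before and after
#' matching/weighting, one row per covariate (or covariate level).
#'
#' @param balance A [balance_table()] result.
#' @param threshold Reference line, conventionally 0.1.
#' @return A ggplot object.
#' @export
plot_balance <- function(balance, threshold = 0.1) {
  d <- dplyr::mutate(
    balance,
    label = ifelse(is.na(.data$level), .data$covariate,
                   paste0(.data$covariate, ": ", .data$level)))
  long <- tidyr::pivot_longer(d, c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd")
  long$stage <- factor(long$stage, c("smd_before", "smd_after"),
                       c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$smd, y = .data$label,
                                     shape = .data$stage,
                                     color = .data$stage)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "absolute standardized mean difference", y = NULL,
                  color = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a prevalence-grid sensitivity analysis
#'
#' Coverage (left) and bias (right) of the robust methods across the
#' exposure-by-outcome prevalence grid.
#'
#' @param metrics A `run_sensitivity("prevalence_grid", ...)` result.
#' @return A ggplot object.
#' @export
plot_prevalence_grid <- function(metrics) {
  d <- dplyr::mutate(metrics, method = method_label(metrics))
  long <- tidyr::pivot_longer(d, c("bias", "cover"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$prev_exposure, y = .data$value,
                               color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$measure),
                        cols = ggplot2::vars(.data$prev_outcome),
                        scales = "free_y") +
    ggplot2::labs(x = "exposure prevalence",
                  y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
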