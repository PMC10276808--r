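# Pseudo-likelihood GLM engine with design-based Taylor-linearization
# (sandwich) covariance for stratified, cluster-sampled data. Point
# estimation is weighted IRLS (stats::glm.fit with quasi families, so
# non-integer analysis weights are legitimate); the variance is the
# with-replacement first-stage linearization: scores are aggregated to PSU
# totals and their between-PSU covariance within strata, scaled by
# n_h / (n_h - 1), is sandwiched between the inverse information.

#' Describe the sampling design of an analysis data set
#'
#' @param stratum,psu Names of the columns holding the stratum and primary
#'   sampling unit (cluster) labels.
#' @return An object of class `svc_design`.
#' @export
svy_design <- function(stratum = "stratum", psu = "bg_id") {
  structure(list(stratum = stratum, psu = psu), class = "svc_design")
}

#' Fit a survey-weighted generalized linear model
#'
#' Solves the weighted pseudo-likelihood score equations for a
#' binomial-logit or Poisson-log model. Coefficients are invariant to a
#' positive rescaling of the weights. If `design` is supplied, the
#' covariance is the design-based linearized (sandwich) estimator with
#' strata and PSU clusters; otherwise it is the model-based inverse
#' information (dispersion fixed at 1).
#'
#' @param data A data frame.
#' @param formula Model formula (response on the left).
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param weights Analysis weights: a column name or a numeric vector.
#'   `NULL` means unweighted.
#' @param offset Offset on the linear-predictor scale (Poisson only): a
#'   column name or numeric vector, used as-is (pass `log(t)` for exposure
#'   time `t`).
#' @param design An [svy_design()] or `NULL`.
#' @return An object of class `svy_glm` with elements `coefficients`,
#'   `vcov`, `se`, `family`, `n`, `converged`, `design_based`,
#'   `lonely_strata` and `aliased`. Methods: [tidy()], [glance()],
#'   `print()`, `coef()`, `vcov()`.
#' @export
svy_glm <- function(data, formula, family = c("binomial", "poisson"),
                    weights = NULL, offset = NULL, design = NULL) {
  family <- match.arg(family)
  w <- resolve_column(weights, data, "weights")
  off <- resolve_column(offset, data, "offset")
  if (!is.null(off) && family != "poisson") {
    stop("an offset is only supported with the poisson-log family",
         call. = FALSE)
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(off)) off <- rep(0, n)
  stopifnot(length(w) == n, length(off) == n)
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial response must be binary 0/1", call. = FALSE)
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    stop("poisson response must be a nonnegative integer count", call. = FALSE)
  }

  # drop aliased (rank-deficient) columns so the information is invertible
  aliased <- character(0)
  qx <- qr(X * sqrt(pmax(w, 1e-12)))
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }

  fam <- if (family == "binomial") stats::quasibinomial() else stats::quasipoisson()
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = w, offset = off, family = fam,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) {
    stop("IRLS did not converge within 100 iterations", call. = FALSE)
  }
  mu <- fit$fitted.values
  beta <- fit$coefficients
  if (family == "binomial" &&
      any((mu < 1e-10 & y == 0) | (mu > 1 - 1e-10 & y == 1)) &&
      max(abs(beta)) > 15) {
    stop("perfect separation detected in the binomial fit", call. = FALSE)
  }

  v <- if (family == "binomial") mu * (1 - mu) else mu
  A <- crossprod(X * sqrt(w * v))
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) solve(A))

  lonely <- 0L
  if (is.null(design)) {
    V <- Ainv
  } else {
    stopifnot(inherits(design, "svc_design"))
    st <- data[[design$stratum]]
    psu <- data[[design$psu]]
    if (is.null(st) || is.null(psu)) {
      stop("design columns not found in `data`", call. = FALSE)
    }
    bd <- between_psu_score_cov(X * (w * (y - mu)), st, psu)
    V <- Ainv %*% bd$B %*% Ainv
    lonely <- bd$lonely
    if (lonely > 0) {
      warning(lonely, " stratum(s) contained a single PSU; their scores were ",
              "centered at the overall mean", call. = FALSE)
    }
  }
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = beta, vcov = V, se = sqrt(pmax(diag(V), 0)),
    family = family, n = n, converged = fit$converged,
    design_based = !is.null(design), lonely_strata = lonely,
    aliased = aliased, fitted = mu
  ), class = "svy_glm")
}

# Between-PSU covariance of weighted score totals within strata, with the
# n_h / (n_h - 1) with-replacement factor. Lonely-PSU strata contribute the
# squared deviation of their single total from the grand mean ("adjust"
# convention).
between_psu_score_cov <- function(U, stratum, psu) {
  key <- paste(stratum, psu, sep = "\r")
  tot <- rowsum(U, key, reorder = TRUE)
  first <- !duplicated(key)
  st_of_psu <- stratum[first][order(key[first])]
  p <- ncol(U)
  B <- matrix(0, p, p)
  grand <- colMeans(tot)
  lonely <- 0L
  for (h in unique(st_of_psu)) {
    rows <- which(st_of_psu == h)
    nh <- length(rows)
    Th <- tot[rows, , drop = FALSE]
    if (nh == 1L) {
      d <- Th[1, ] - grand
      B <- B + tcrossprod(d)
      lonely <- lonely + 1L
    } else {
      ctr <- sweep(Th, 2, colMeans(Th))
      B <- B + nh / (nh - 1) * crossprod(ctr)
    }
  }
  list(B = B, lonely = lonely)
}

resolve_column <- function(x, data, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (is.null(data[[x]])) stop(what, " column `", x, "` not found",
                                 call. = FALSE)
    return(data[[x]])
  }
  as.numeric(x)
}

#' Wald confidence interval for a fitted coefficient
#'
#' @param fit An [svy_glm()] fit.
#' @param term Coefficient name.
#' @param level Confidence level (default 0.95).
#' @param exponentiate Return the interval on the ratio (exp) scale?
#' @return Named vector `c(lo, hi)`.
#' @export
wald_interval <- function(fit, term, level = 0.95, exponentiate = FALSE) {
  stopifnot(inherits(fit, "svy_glm"), term %in% names(fit$coefficients))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  ci <- c(lo = est - z * se, hi = est + z * se)
  if (exponentiate) exp(ci) else ci
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a survey-weighted GLM fit
#'
#' @param x An [svy_glm()] object.
#' @param conf.int,conf.level Include Wald confidence limits.
#' @param exponentiate Report estimates and limits on the ratio scale.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` and optionally
#'   `conf.low`/`conf.high`.
#' @method tidy svy_glm
#' @export
tidy.svy_glm <- function(x, conf.int = TRUE, conf.level = 0.95,
                         exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' Glance at a survey-weighted GLM fit
#'
#' @param x An [svy_glm()] object.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @method glance svy_glm
#' @export
glance.svy_glm <- function(x, ...) {
  tibble::tibble(
    n = x$n, df = length(x$coefficients), family = x$family,
    converged = x$converged, design_based = x$design_based,
    lonely_strata = x$lonely_strata
  )
}

#' @export
coef.svy_glm <- function(object, ...) object$coefficients

#' @export
vcov.svy_glm <- function(object, ...) object$vcov

#' @export
print.svy_glm <- function(x, ...) {
  cat("Survey-weighted GLM (", x$family, "-",
      if (x$family == "binomial") "logit" else "log", "), n = ", x$n,
      if (x$design_based) ", design-based SEs" else ", model-based SEs",
      "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}
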