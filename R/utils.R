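#' Inverse-logit (expit) transform
#'
#' @param x Numeric vector on the logit scale.
#' @return `exp(x) / (1 + exp(x))`, computed stably for large `|x|`.
#' @export
expit <- function(x) {
  stats::plogis(x)
}

#' Logit transform
#'
#' @param p Probabilities in (0, 1).
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p) {
  stats::qlogis(p)
}

# Deterministic sub-seed for a named random-number substream. Each variable
# family (ages, BMI, exposure, replicate r, ...) gets its own stream so a
# component can be regenerated independently of the draw order elsewhere.
# Kept below 2^31 - 1 so the result is a valid integer seed.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars) * 97)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, label, expr) {
  set.seed(substream_seed(seed, label))
  expr
}

# Weighted mean / variance with normalized weights (population-style
# denominator sum(w)); used by balance diagnostics.
weighted_mean <- function(x, w) {
  sum(w * x) / sum(w)
}

weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
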