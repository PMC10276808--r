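# Shared miniature populations and independent oracles used across tests.
# Heavy objects are built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_pop <- function() {
  fixture("small_pop", function() {
    generate_population(pop_config(n_bg = 80, hh_per_bg_mean = 60), seed = 3)
  })
}

small_sample <- function() {
  fixture("small_sample", function() {
    draw_survey_sample(small_pop(), scenario = 1, seed = 5,
                       bg_prob = rep(0.7, 8), hh_prob = 0.5)
  })
}

# Brute-force greedy matcher: processes exposed units in descending score
# order; each scans every still-available unexposed unit and takes the
# minimum |distance|, ties broken by lowest original index (which.min picks
# the first minimum in index order).
brute_force_match <- function(e1, e0) {
  avail <- rep(TRUE, length(e0))
  ord1 <- order(-e1, seq_along(e1))
  n_pairs <- min(length(e1), length(e0))
  out <- matrix(0L, n_pairs, 2L)
  k <- 0L
  for (i in ord1) {
    if (!any(avail)) break
    d <- abs(e0 - e1[i])
    d[!avail] <- Inf
    j <- which.min(d)
    k <- k + 1L
    out[k, ] <- c(i, j)
    avail[j] <- FALSE
  }
  out[seq_len(k), , drop = FALSE]
}

# Textbook sandwich covariance for a weighted logit/log GLM with one PSU
# per observation in a single stratum, computed from first principles.
textbook_sandwich <- function(X, y, mu, w, family) {
  v <- if (family == "binomial") mu * (1 - mu) else mu
  A <- crossprod(X * sqrt(w * v))
  U <- X * (w * (y - mu))
  n <- nrow(X)
  ctr <- sweep(U, 2, colMeans(U))
  B <- n / (n - 1) * crossprod(ctr)
  solve(A) %*% B %*% solve(A)
}
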