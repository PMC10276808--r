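# Greedy 1:1 nearest-neighbour propensity score matching without
# replacement, and inherited survey weights (ISW) for matched pairs.

#' Greedy 1:1 propensity score matching without replacement
#'
#' Exposed units are processed in descending order of their estimated
#' propensity score; each takes the still-unmatched unexposed unit with the
#' smallest absolute score distance `|e_i - e_j|`. Ties in distance are
#' broken by the lowest row index. Unmatched unexposed units are discarded,
#' so the pair count is `min(n_exposed, n_unexposed)`. No caliper is
#' applied.
#'
#' @param data A data frame containing the exposure column.
#' @param e_hat Estimated propensity scores, one per row of `data` (or an
#'   [estimate_propensity()] result).
#' @param exposure Name of the binary exposure column.
#' @return A tibble of class `svc_matched` with columns `exposed` and
#'   `unexposed` (row indices into `data`) and `distance`; attribute
#'   `matched_rows` holds the sorted row indices of all matched units.
#' @export
psm_match <- function(data, e_hat, exposure = "insomnia") {
  if (inherits(e_hat, "svc_propensity")) e_hat <- e_hat$e_hat
  z <- data[[exposure]]
  stopifnot(length(e_hat) == nrow(data), all(z %in% c(0, 1)))
  if (!any(z == 1) || !any(z == 0)) {
    stop("both exposure groups must be nonempty for matching", call. = FALSE)
  }
  idx1 <- which(z == 1)
  idx0 <- which(z == 0)
  pairs <- greedy_match_core(e_hat[idx1], e_hat[idx0])
  out <- tibble::tibble(
    exposed = idx1[pairs[, 1]],
    unexposed = idx0[pairs[, 2]],
    distance = abs(e_hat[idx1[pairs[, 1]]] - e_hat[idx0[pairs[, 2]]])
  )
  attr(out, "matched_rows") <- sort(c(out$exposed, out$unexposed))
  class(out) <- c("svc_matched", class(out))
  out
}

# Core matcher on score vectors. Returns a 2-column matrix of positions
# into (e1, e0). Unexposed scores are kept in a sorted doubly-bridged
# structure (lf/rf jump pointers over removed slots) so each exposed unit
# finds its nearest remaining neighbour in amortized near-constant time.
greedy_match_core <- function(e1, e0) {
  n1 <- length(e1)
  n0 <- length(e0)
  ord0 <- order(e0, seq_along(e0))   # stable: ascending score, then index
  es <- e0[ord0]
  ord1 <- order(-e1, seq_along(e1))  # descending score, then index
  n_pairs <- min(n1, n0)

  alive <- rep(TRUE, n0)
  lf <- seq_len(n0) - 1L   # jump target when walking left past dead slots
  rf <- seq_len(n0) + 1L   # jump target when walking right
  left_alive <- function(j) {
    while (j >= 1L && !alive[j]) j <- lf[j]
    j
  }
  right_alive <- function(j) {
    while (j <= n0 && !alive[j]) j <- rf[j]
    j
  }

  pos1 <- findInterval(e1[ord1], es)  # static sorted positions
  out <- matrix(0L, n_pairs, 2L)
  k <- 0L
  for (m in seq_along(ord1)) {
    if (k >= n_pairs) break
    t <- e1[ord1[m]]
    l <- left_alive(pos1[m])
    r <- right_alive(pos1[m] + 1L)
    dl <- if (l >= 1L) t - es[l] else Inf
    dr <- if (r <= n0) es[r] - t else Inf
    best <- min(dl, dr)
    # gather every remaining candidate at the minimal distance and take the
    # lowest original row index (deterministic tie-break)
    cand <- integer(0)
    j <- l
    while (j >= 1L && (t - es[j]) == best) {
      cand <- c(cand, j)
      j <- left_alive(j - 1L)
    }
    j <- r
    while (j <= n0 && (es[j] - t) == best) {
      cand <- c(cand, j)
      j <- right_alive(j + 1L)
    }
    win <- cand[which.min(ord0[cand])]
    k <- k + 1L
    out[k, ] <- c(ord1[m], ord0[win])
    alive[win] <- FALSE
    lf[win] <- win - 1L
    rf[win] <- win + 1L
  }
  out[seq_len(k), , drop = FALSE]
}

#' Inherited survey weights for a matched sample
#'
#' Exposed units keep their own survey weight; each matched unexposed unit
#' inherits the weight of the exposed partner it was matched to, so the two
#' members of a pair carry equal weights.
#'
#' @param matched A [psm_match()] result.
#' @param data The data frame that was matched.
#' @param weight_col Name of the survey-weight (OSW) column.
#' @return A named numeric vector of ISW indexed like
#'   `attr(matched, "matched_rows")`, i.e. one weight per matched row of
#'   `data`, in row order.
#' @export
assign_isw <- function(matched, data, weight_col = "weight") {
  stopifnot(inherits(matched, "svc_matched"))
  osw <- data[[weight_col]]
  rows <- attr(matched, "matched_rows")
  isw <- numeric(length(rows))
  names(isw) <- rows
  isw[as.character(matched$exposed)] <- osw[matched$exposed]
  isw[as.character(matched$unexposed)] <- osw[matched$exposed]
  unname(isw[as.character(rows)])
}
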