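#' Community trait series along a frequency trajectory
#'
#' Evaluates the mean interaction trait `q(z)`, the mean invasibility
#' `Q(z)` and their difference (the "selfishness" `q - Q = sum_i
#' alpha_ii z_i`) at every stored time of a replicator trajectory.  In
#' competitive-exclusion runs `Q -> 0` while `q` tends to the winner's
#' self-interaction deviation; in the oscillatory large-`mu` regime both
#' fluctuate, alternating between higher average competition and higher
#' average facilitation.
#'
#' @param traj list with `tau` and `z` from [integrate_replicator()].
#' @param A normalized interaction matrix.
#' @param Lambda invasion fitness matrix built from `A`.
#' @return Data frame with columns `tau`, `q`, `Q`, `selfishness`.
#' @export
trait_trajectory <- function(traj, A, Lambda) {
  out <- t(apply(traj$z, 1L, function(z) {
    tr <- community_traits(z, A, Lambda)
    c(tr$q, tr$Q, tr$selfishness)
  }))
  data.frame(tau = traj$tau, q = out[, 1L], Q = out[, 2L],
             selfishness = out[, 3L])
}

#' Effective mean interaction coefficient
#'
#' The community-level mean co-colonization coefficient shifts with the
#' mean trait: `k_effective(t) = k + eps * q(t)`.
#'
#' @param k baseline mean interaction coefficient.
#' @param eps deviation scale.
#' @param q_series numeric vector of mean-trait values.
#' @return Numeric vector `k + eps * q_series`.
#' @export
effective_mean_interaction <- function(k, eps, q_series) {
  k + eps * q_series
}

#' Count mean crossings of a series
#'
#' Simple oscillation diagnostic: the number of times a series crosses its
#' own mean.  More than four crossings over the analysis window is treated
#' as fluctuating selection.
#'
#' @param x numeric series.
#' @return Integer crossing count.
#' @export
count_mean_crossings <- function(x) {
  s <- sign(x - mean(x))
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Lagged correlation between the two community trait series
#'
#' Diagnostic for synchrony/asynchrony of `q` and `Q` oscillations: the
#' Pearson correlation of `q(tau)` against `Q(tau + lag)` over the common
#' window, for a grid of integer index lags.
#'
#' @param traits data frame from [trait_trajectory()].
#' @param max_lag maximum index lag to scan.
#' @return Data frame with `lag` (in indices) and `correlation`.
#' @export
trait_lag_correlation <- function(traits, max_lag = 50L) {
  q <- traits$q
  Q <- traits$Q
  n <- length(q)
  max_lag <- min(max_lag, n - 2L)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) cor(q[seq_len(n - l)], Q[seq_len(n - l) + l])
    else cor(q[seq_len(n + l) - l], Q[seq_len(n + l)])
  }, 0)
  data.frame(lag = lags, correlation = cc)
}
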