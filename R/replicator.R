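#' Pairwise invasion fitness matrix
#'
#' Builds the matrix `Lambda = (lambda_ij)` of pairwise invasion fitnesses
#' from the normalized interaction matrix and the single-to-co-colonization
#' ratio:
#' \deqn{\lambda_{ij} = \alpha_{ji} - \alpha_{jj} - \mu(\alpha_{ij} - \alpha_{ji}),}
#' the initial growth rate of a rare invader i in the endemic equilibrium
#' where only strain j is resident.  The diagonal is structurally zero.  At
#' `mu = 0` invasion depends only on the resident's column of `A`; as
#' `mu -> Inf`, `Lambda/mu -> t(A) - A` (skew-symmetric limit).
#'
#' @param A normalized interaction matrix (square).
#' @param mu single-to-co-colonization ratio, `mu >= 0`.
#' @return `N x N` matrix with attribute `mu`; zero diagonal.
#' @export
#' @examples
#' invasion_fitness_matrix(rbind(c(0, 1), c(-1, 0)), mu = 1)
invasion_fitness_matrix <- function(A, mu) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("invalid parameter: mu must be a single non-negative number")
  A <- unclass(A)
  attributes(A) <- attributes(A)["dim"]
  # lambda_ij = alpha_ji - alpha_jj - mu*(alpha_ij - alpha_ji):
  # t(A)[i,j] = alpha_ji; alpha_jj varies along columns -> byrow = TRUE
  L <- t(A) - matrix(diag(A), nrow(A), ncol(A), byrow = TRUE) -
    mu * (A - t(A))
  diag(L) <- 0
  attr(L, "mu") <- mu
  L
}

#' Classify a pairwise outcome from the two invasion fitnesses
#'
#' The four generic outcomes between two strains: both can invade each
#' other (`coexistence`), neither can (`bistability`, i.e. priority
#' effects), or exactly one can (competitive exclusion of the strain that
#' cannot invade).  An exact zero is reported as `degenerate`.
#'
#' @param lambda_ij invasion fitness of i against resident j (vectorized).
#' @param lambda_ji invasion fitness of j against resident i.
#' @return Character vector in `{"coexistence", "bistability",
#'   "exclusion_of_i", "exclusion_of_j", "degenerate"}`.
#' @export
#' @examples
#' classify_pair(2, 1)    # coexistence
#' classify_pair(-1, -2)  # bistability
classify_pair <- function(lambda_ij, lambda_ji) {
  out <- character(length(lambda_ij))
  out[lambda_ij > 0 & lambda_ji > 0] <- "coexistence"
  out[lambda_ij < 0 & lambda_ji < 0] <- "bistability"
  out[lambda_ij > 0 & lambda_ji < 0] <- "exclusion_of_j"
  out[lambda_ij < 0 & lambda_ji > 0] <- "exclusion_of_i"
  out[lambda_ij == 0 | lambda_ji == 0] <- "degenerate"
  out
}

#' Replicator vector field
#'
#' `dz_i/dtau = Theta * z_i * ((Lambda z)_i - Q(z))` with
#' `Q(z) = z' Lambda z` (with zero diagonal this equals the off-diagonal
#' pair sum).  The components sum to zero exactly on the simplex, so the
#' simplex is invariant.
#'
#' @param z frequency vector on the simplex.
#' @param Lambda pairwise invasion fitness matrix (zero diagonal).
#' @param Theta selection speed (default 1; it only rescales time).
#' @return Derivative vector `dz/dtau`.
#' @export
replicator_rhs <- function(z, Lambda, Theta = 1) {
  w <- as.vector(Lambda %*% z)
  Theta * z * (w - sum(z * w))
}

#' Integrate the replicator equation
#'
#' Numerical integration of the reduced N-dimensional frequency dynamics,
#' performed in log-frequency coordinates `u_i = log z_i` (with
#' `du_i/dtau = Theta ((Lambda z)_i - Q(z))`).  This keeps boundary faces
#' exactly invariant, never floors small positive frequencies (heteroclinic
#' excursions can dip to ~1e-300 and rebound), and preserves the simplex to
#' 1e-10 (frequencies are renormalized at output times).  Strains starting
#' at exactly zero remain at zero, as in the exact dynamics.
#'
#' @param z0 initial frequencies on the simplex.
#' @param Lambda invasion fitness matrix.
#' @param Theta selection speed.
#' @param tau_max slow-time horizon.
#' @param n_out number of output times.
#' @param times optional explicit non-decreasing output time grid starting
#'   at 0 (overrides `tau_max`/`n_out`).
#' @param rtol,atol integrator tolerances (on the log frequencies).
#' @return List with `tau` (vector) and `z` (times x N matrix).
#' @export
integrate_replicator <- function(z0, Lambda, Theta = 1, tau_max = 100,
                                 n_out = 1001L, times = NULL,
                                 rtol = 1e-10, atol = 1e-10) {
  if (abs(sum(z0) - 1) > 1e-10 || any(z0 < 0))
    stop("z0 must lie on the probability simplex")
  N <- length(z0)
  if (is.null(times)) times <- seq(0, tau_max, length.out = n_out)
  if (length(times) < 2L || max(times) == 0) {
    z <- matrix(z0, nrow = max(1L, length(times)), ncol = N, byrow = TRUE)
    return(list(tau = if (length(times)) times else 0, z = z))
  }
  active <- z0 > 0
  La <- unclass(Lambda)[active, active, drop = FALSE]
  rhs <- function(t, u, parms) {
    z <- exp(u - max(u))
    z <- z / sum(z)
    w <- as.vector(La %*% z)
    list(Theta * (w - sum(z * w)))
  }
  sol <- deSolve::ode(y = log(z0[active]), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrator failure; last valid tau ", max(sol[, 1L]))
  u <- sol[, -1L, drop = FALSE]
  za <- exp(u - apply(u, 1L, max))
  za <- za / rowSums(za)
  z <- matrix(0, nrow(za), N)
  z[, active] <- za
  dimnames(z) <- NULL
  list(tau = sol[, 1L], z = z)
}

#' Community-level traits
#'
#' The mean interaction trait `q(z) = sum_{j,k} alpha_jk z_k z_j` (all
#' pairs, diagonal included), the mean invasibility
#' `Q(z) = sum_{j != k} lambda_jk z_j z_k`, and the "selfishness"
#' `q - Q`, which identically equals `sum_i alpha_ii z_i` for every `mu`
#' because the mu-dependent part of `Q` is an antisymmetric quadratic form.
#'
#' @param z frequency vector on the simplex.
#' @param A normalized interaction matrix.
#' @param Lambda invasion fitness matrix built from `A`.
#' @return List with `q`, `Q`, `selfishness`.
#' @export
community_traits <- function(z, A, Lambda) {
  A <- unclass(A)
  q <- as.vector(t(z) %*% A %*% z)
  Q <- as.vector(t(z) %*% Lambda %*% z)
  list(q = q, Q = Q, selfishness = q - Q)
}

#' Rescaled replicator field in the single-colonization limit
#'
#' As `mu -> Inf` the rescaled invasion matrix `Lambda/mu` tends to the
#' skew-symmetric `t(A) - A`, for which the quadratic term vanishes
#' (`z'(t(A)-A)z = 0`) and the dynamics reduce to the zero-sum replicator
#' `dz_i = Theta_lim * z_i * (((t(A)-A) z)_i)`.  The simplex is preserved
#' without the mean-fitness correction; interior equilibria are neutrally
#' stable centers surrounded by a one-parameter family of cycles.
#'
#' @param z frequency vector on the simplex.
#' @param A normalized interaction matrix.
#' @param Theta_lim limiting speed constant.
#' @return Derivative vector.
#' @export
rescaled_large_mu_rhs <- function(z, A, Theta_lim = 1) {
  A <- unclass(A)
  Theta_lim * z * as.vector((t(A) - A) %*% z)
}

#' Integrate the skew-limit replicator
#'
#' @inheritParams rescaled_large_mu_rhs
#' @param z0 initial frequencies.
#' @param tau_max,n_out,rtol,atol as in [integrate_replicator()].
#' @return List with `tau` and `z`.
#' @export
integrate_skew_limit <- function(z0, A, Theta_lim = 1, tau_max = 100,
                                 n_out = 1001L, rtol = 1e-10, atol = 1e-12) {
  S <- t(unclass(A)) - unclass(A)
  attr(S, "mu") <- Inf
  integrate_replicator(z0, S, Theta = Theta_lim, tau_max = tau_max,
                       n_out = n_out, rtol = rtol, atol = atol)
}

#' Classify the attractor of a replicator trajectory
#'
#' Heuristic classification of the long-run behaviour of a trajectory into
#' `fixed_point`, `limit_cycle`, `heteroclinic_like`, or `undetermined`:
#' * `fixed_point`: the vector field norm at the final state is below 1e-8
#'   and the state lies within 1e-6 of an enumerated stable equilibrium;
#' * `heteroclinic_like`: the log running-minimum frequency decreases
#'   approximately linearly (slope below `-1e-3` per tau, R^2 > 0.9 over the
#'   last half) while some strain still exceeds frequency 0.9, or a
#'   frequency underflows below ~1e-300 (effective absorption on the
#'   boundary);
#' * `limit_cycle`: frequency peaks recur with a stable period and minima
#'   bounded away from zero;
#' * otherwise `undetermined` (the honest fallback).
#'
#' Converging spirals are classified as `fixed_point` (they reach the
#' steady state); the trajectory should span at least ~10 periods of its
#' slowest visible oscillation for the cycle test to be meaningful.
#'
#' @param traj list with `tau` and `z` from [integrate_replicator()].
#' @param Lambda invasion fitness matrix that generated the trajectory.
#' @param Theta selection speed used.
#' @return A single classification string.
#' @export
classify_attractor <- function(traj, Lambda, Theta = 1) {
  z <- traj$z
  tau <- traj$tau
  nT <- nrow(z)
  zT <- z[nT, ]
  dz <- replicator_rhs(zT, Lambda, Theta)
  if (sqrt(sum(dz^2)) < 1e-8) {
    recs <- stability(enumerate_equilibria(Lambda, keep_infeasible = FALSE))
    st <- recs[recs$stable, , drop = FALSE]
    if (nrow(st) > 0) {
      zcols <- grep("^z[0-9]+$", names(st))
      d <- apply(st[, zcols, drop = FALSE], 1L,
                 function(r) max(abs(r - zT)))
      if (min(d) < 1e-6) return("fixed_point")
    }
  }
  act <- z[1L, ] > 0  # strains absent from the start stay on their face
  z <- z[, act, drop = FALSE]
  half <- tau >= tau[nT] / 2
  zh <- z[half, , drop = FALSE]
  if (min(z) < 1e-300) return("heteroclinic_like")
  # heteroclinic signature: geometric decay of the running minimum while
  # single strains keep dominating
  runmin <- cummin(apply(z, 1L, min))
  lr <- log(pmax(runmin[half], 1e-320))
  th <- tau[half]
  if (length(unique(lr)) > 2) {
    fit <- lm(lr ~ th)
    slope <- coef(fit)[2L]
    r2 <- summary(fit)$r.squared
    if (is.finite(slope) && slope < -1e-3 && r2 > 0.9 &&
        max(apply(zh, 1L, max)) > 0.9)
      return("heteroclinic_like")
  }
  # limit cycle: recurring peaks with a stable period, minima bounded away
  v <- apply(zh, 2L, stats::var)
  x <- zh[, which.max(v)]
  dx <- diff(x)
  peaks <- which(dx[-length(dx)] > 0 & dx[-1L] <= 0) + 1L
  if (length(peaks) >= 3L && min(zh) > 1e-4) {
    periods <- diff(th[peaks])
    if (mean(periods) > 0 &&
        stats::sd(periods) / mean(periods) < 0.1 &&
        diff(range(x)) > 1e-4)
      return("limit_cycle")
  }
  "undetermined"
}
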