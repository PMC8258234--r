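#' Right-hand side of the full compartmental co-colonization model
#'
#' Derivatives of the N + N^2 + 1 compartment SIS model with
#' co-colonization: susceptibles `S`, singly colonized `I_i`, and ordered
#' co-colonization compartments `I_ij` (hosts first colonized by i, then by
#' j; `I_ij` and `I_ji` are distinct variables, `I_ii` is allowed).  The
#' force of infection of strain i is
#' `F_i = beta * (I_i + sum_j (I_ij + I_ji)/2)` and
#' \deqn{dS = m(1-S) - S \sum_j F_j, \quad
#'       dI_i = F_i S - m I_i - I_i \sum_j K_{ij} F_j, \quad
#'       dI_{ij} = I_i K_{ij} F_j - m I_{ij}.}
#'
#' @param state list with components `S` (scalar), `I` (length-N vector) and
#'   `Iij` (N x N matrix of ordered co-colonization proportions).
#' @param K co-colonization susceptibility matrix, entries must be
#'   non-negative.
#' @param beta transmission rate.
#' @param m infected-host turnover rate.
#' @return A list with components `S`, `I`, `Iij` holding the derivatives.
#' @export
full_rhs <- function(state, K, beta, m) {
  if (any(K < 0)) stop("unphysical parameter: negative K entries")
  attributes(K) <- attributes(K)["dim"]
  N <- length(state$I)
  stopifnot(is.matrix(state$Iij), nrow(state$Iij) == N, ncol(state$Iij) == N)
  Fi <- beta * (state$I + 0.5 * (rowSums(state$Iij) + colSums(state$Iij)))
  dS <- m * (1 - state$S) - state$S * sum(Fi)
  dI <- Fi * state$S - m * state$I - state$I * as.vector(K %*% Fi)
  dIij <- (state$I * K) * matrix(Fi, N, N, byrow = TRUE) - m * state$Iij
  list(S = dS, I = dI, Iij = dIij)
}

# Packed-vector version used by the integrator.
sis_rhs_packed <- function(t, y, parms) {
  N <- parms$N
  S <- y[1L]
  I <- y[2L:(N + 1L)]
  M <- matrix(y[(N + 2L):(N + 1L + N * N)], N, N)
  Fi <- parms$beta * (I + 0.5 * (rowSums(M) + colSums(M)))
  dS <- parms$m * (1 - S) - S * sum(Fi)
  dI <- Fi * S - parms$m * I - I * as.vector(parms$K %*% Fi)
  dM <- (I * parms$K) * matrix(Fi, N, N, byrow = TRUE) - parms$m * M
  list(c(dS, dI, as.vector(dM)))
}

#' Integrate the full compartmental model
#'
#' Stiff-capable numerical integration of the full SIS co-colonization
#' system.  Total host mass `S + sum(I) + sum(Iij)` obeys
#' `dT/dt = m (1 - T)` exactly, so trajectories started at total mass 1
#' conserve it; this is checked to 1e-8.  Tiny negative excursions within
#' the integrator tolerance band are clamped to zero; larger negativity
#' aborts with a diagnostic.
#'
#' @param state0 initial state: list with `S`, `I`, `Iij` (total mass 1).
#' @param K interaction matrix (non-negative entries).
#' @param beta,m transmission and turnover rates.
#' @param horizon final time (integration starts at 0).
#' @param n_out number of equally spaced output times (including 0).
#' @param rtol,atol relative / absolute integrator tolerances.
#' @return An object of class `sis_trajectory`: list with `times`, `S`
#'   (vector), `I` (times x N matrix), `Iij` (times x N x N array), and the
#'   parameters.
#' @export
integrate_full <- function(state0, K, beta, m, horizon, n_out = 201L,
                           rtol = 1e-8, atol = 1e-10) {
  if (any(K < 0)) stop("unphysical parameter: negative K entries")
  N <- length(state0$I)
  y0 <- c(state0$S, state0$I, as.vector(state0$Iij))
  mass0 <- sum(y0)
  if (abs(mass0 - 1) > 1e-8)
    stop("initial state must have total mass 1 (got ", format(mass0), ")")
  if (horizon < 0) stop("horizon must be non-negative")
  times <- if (horizon == 0) c(0, 0) else seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = sis_rhs_packed,
                      parms = list(N = N, K = unclass(K), beta = beta, m = m),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrator failure; last valid time ", max(sol[, 1L]))
  y <- sol[, -1L, drop = FALSE]
  dimnames(y) <- NULL
  neg <- min(y)
  if (neg < -1e-8)
    stop("state went negative beyond tolerance (min = ", format(neg), ")")
  y[y < 0] <- 0
  mass <- rowSums(y)
  if (max(abs(mass - 1)) > 1e-8)
    stop("mass conservation violated: max |T - 1| = ",
         format(max(abs(mass - 1))))
  tt <- sol[, 1L]
  if (horizon == 0) {
    tt <- tt[1L]
    y <- y[1L, , drop = FALSE]
  }
  structure(list(times = tt,
                 S = y[, 1L],
                 I = y[, 2L:(N + 1L), drop = FALSE],
                 Iij = array(y[, (N + 2L):(N + 1L + N * N)],
                             dim = c(length(tt), N, N)),
                 N = N, beta = beta, m = m, K = K),
            class = "sis_trajectory")
}

#' Build a slow-manifold state from strain frequencies
#'
#' Constructs the full-model state corresponding to given strain frequencies
#' `z` on the neutral endemic manifold: `I_i = I * z_i`,
#' `I_ij = D * z_i * z_j`, `S = 1/R0`, where `S, I, D` are the conserved
#' neutral prevalences.  Used to start validation runs past the fast
#' transient.
#'
#' @param z0 frequency vector on the simplex.
#' @param beta,m,k mean-field parameters.
#' @return A state list suitable for [integrate_full()].
#' @export
slow_manifold_state <- function(z0, beta, m, k) {
  if (abs(sum(z0) - 1) > 1e-10 || any(z0 < 0))
    stop("z0 must lie on the probability simplex")
  p <- conserved_prevalences(beta / m, k)
  list(S = p$S, I = p$I * z0, Iij = p$D * outer(z0, z0))
}

#' Strain frequencies along a full-model trajectory
#'
#' Two frequency readouts: from single colonization,
#' `z_i = I_i / sum_j I_j`, and from co-colonization,
#' `z_i' = D_i / sum_j D_j` with `D_i = sum_j (I_ij + I_ji)/2`.  On the slow
#' manifold the two agree to first order in the deviation scale.
#'
#' @param traj an object from [integrate_full()].
#' @return List with `times`, `z_single`, `z_double` (times x N matrices).
#' @export
extract_strain_frequencies <- function(traj) {
  stopifnot(inherits(traj, "sis_trajectory"))
  Itot <- rowSums(traj$I)
  if (any(Itot <= 0))
    stop("undefined frequency: all strains extinct at some output time")
  zs <- traj$I / Itot
  Di <- 0.5 * (apply(traj$Iij, c(1, 2), sum) + apply(traj$Iij, c(1, 3), sum))
  zd <- Di / rowSums(Di)
  list(times = traj$times, z_single = zs, z_double = zd)
}

#' Validate the replicator reduction against the full model
#'
#' Integrates the full compartmental model from a slow-manifold initial
#' condition and the reduced replicator equation from the same frequencies,
#' and reports the worst-case discrepancy over a fixed slow-time window
#' `tau in [0, tau_max]` (real time `t = tau/eps`).  Also checks the
#' reconstruction `I_i = I z_i`, `I_ij = D z_i z_j` against the full-model
#' compartments.  The discrepancy scales as O(eps).
#'
#' @param A normalized interaction matrix.
#' @param beta,m,k mean-field parameters (`beta/m > 1`).
#' @param eps deviation scale (small, `<= 0.1` recommended).
#' @param z0 initial frequencies on the simplex.
#' @param tau_max slow-time window length.
#' @param n_out number of comparison times.
#' @return List with `sup_z_error` (max abs frequency discrepancy),
#'   `sup_recon_error` (max abs compartment reconstruction error), `eps`,
#'   and the two frequency trajectories.
#' @export
validate_reduction <- function(A, beta, m, k, eps, z0, tau_max = 5,
                               n_out = 101L) {
  ctx <- mean_field_context(beta, m, k)
  K <- build_interaction_matrix(A, k, eps)
  if (any(K < 0)) stop("unphysical parameter: negative K entries")
  state0 <- slow_manifold_state(z0, beta, m, k)
  if (eps == 0) {
    horizon <- tau_max  # neutral: any window; both models are constant in z
  } else {
    horizon <- tau_max / eps
  }
  traj <- integrate_full(state0, K, beta, m, horizon, n_out = n_out)
  freq <- extract_strain_frequencies(traj)
  L <- invasion_fitness_matrix(A, ctx$mu)
  taus <- eps * traj$times
  rep_traj <- integrate_replicator(z0, L, Theta = ctx$theta,
                                   tau_max = max(taus, 0), times = taus)
  z_rep <- rep_traj$z
  sup_z <- max(abs(freq$z_single - z_rep))
  I_rec <- ctx$I * z_rep
  sup_recon <- max(abs(traj$I - I_rec))
  for (ti in seq_along(traj$times)) {
    Mij <- ctx$D * outer(z_rep[ti, ], z_rep[ti, ])
    sup_recon <- max(sup_recon, max(abs(traj$Iij[ti, , ] - Mij)))
  }
  list(sup_z_error = sup_z, sup_recon_error = sup_recon, eps = eps,
       times = traj$times, z_full = freq$z_single, z_replicator = z_rep)
}
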