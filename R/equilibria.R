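#' Enumerate candidate steady states of the replicator system by support
#'
#' For every nonempty subset J of strains, solves the linear system
#' `(Lambda z)_i = c` for `i` in J with `sum(z[J]) = 1` and `z = 0`
#' off-support, records feasibility (all solved frequencies strictly
#' positive beyond tolerance), the simplex-restricted Jacobian's dominant
#' eigenvalue real part, local stability, Shannon entropy, and the largest
#' off-support invasion rate.  Vertices (single-strain supports) are always
#' equilibria.  Singular support systems are recorded as degenerate, not
#' errors.  Enumeration is exhaustive over `2^N - 1` supports, with a guard
#' at `N <= 16`.
#'
#' @param Lambda pairwise invasion fitness matrix (square, zero diagonal).
#' @param tol_feas feasibility tolerance on solved frequencies (1e-9).
#' @param cond_tol condition-number threshold above which a support system
#'   is declared degenerate (1e12).
#' @param tol_eig eigenvalue stability tolerance (absolute, on the
#'   `Theta = 1` normalized Jacobian).
#' @param keep_infeasible keep rows for infeasible/degenerate supports
#'   (default TRUE; ensemble code drops them for speed).
#' @return A data frame with one row per support: `support` (bitmask,
#'   bit i-1 set when strain i is present), `n` (support size), `feasible`,
#'   `degenerate`, `growth` (the common growth value `c`, which equals
#'   `Q(z*)`), `dominant_real`, `marginal`, `stable`, `entropy`,
#'   `max_invasion` (largest off-support invasion rate; `-Inf` for full
#'   support), and frequency columns `z1..zN`.
#' @export
#' @examples
#' L <- rbind(c(0, 2), c(1, 0))
#' enumerate_equilibria(L)  # two vertices plus interior (2/3, 1/3)
enumerate_equilibria <- function(Lambda, tol_feas = 1e-9, cond_tol = 1e12,
                                 tol_eig = 1e-8, keep_infeasible = TRUE) {
  if (!is.matrix(Lambda) || nrow(Lambda) != ncol(Lambda))
    stop("Lambda must be a square matrix")
  if (max(abs(diag(Lambda))) > 1e-12)
    stop("Lambda must have (structurally) zero diagonal")
  if (nrow(Lambda) > 16L)
    stop("support enumeration limited to N <= 16")
  raw <- enum_equilibria_cpp(unclass(Lambda), tol_feas, cond_tol, tol_eig,
                             keep_infeasible, TRUE)
  z <- t(raw$z)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- data.frame(support = raw$support, n = raw$n,
                    feasible = raw$feasible, degenerate = raw$degenerate,
                    growth = raw$growth, dominant_real = raw$dominant_real,
                    marginal = raw$marginal, stable = raw$stable,
                    entropy = raw$entropy, max_invasion = raw$max_invasion)
  cbind(out, as.data.frame(z))
}

#' Jacobian of the replicator field restricted to the simplex
#'
#' Full `N x N` Jacobian of the replicator equation at a candidate
#' equilibrium, together with the spectrum of its restriction to the
#' simplex tangent space `{v : sum(v) = 0}` (computed in an orthonormal
#' tangent basis, which excludes the spurious direction normal to the
#' simplex).  For off-support strains the retained spectrum contains the
#' invasion rates `Theta * ((Lambda z*)_i - Q(z*))`.  `Theta` multiplies
#' the whole field, so it scales every eigenvalue without affecting
#' stability classification.
#'
#' @param z_star candidate equilibrium on the simplex.
#' @param Lambda invasion fitness matrix.
#' @param Theta selection speed.
#' @return List with `jacobian` (N x N), `spectrum` (N-1 complex
#'   eigenvalues), and `dominant_real`.
#' @export
simplex_jacobian <- function(z_star, Lambda, Theta = 1) {
  N <- length(z_star)
  L <- unclass(Lambda)
  w <- as.vector(L %*% z_star)
  Q <- sum(z_star * w)
  u <- as.vector((L + t(L)) %*% z_star)
  J <- z_star * (L - matrix(u, N, N, byrow = TRUE))
  diag(J) <- diag(J) + (w - Q)
  J <- Theta * J
  if (N == 1L)
    return(list(jacobian = J, spectrum = complex(0), dominant_real = -Inf))
  E <- qr.Q(qr(cbind(rep(1, N), diag(N))))[, 2:N, drop = FALSE]
  spec <- eigen(t(E) %*% J %*% E, only.values = TRUE)$values
  list(jacobian = J, spectrum = spec, dominant_real = max(Re(spec)))
}

#' Apply the stability rule to equilibrium records
#'
#' A record is stable iff it is feasible and the dominant real part of its
#' simplex-restricted spectrum is below `-tol_eig`; records with
#' `|dominant_real| <= tol_eig` are marked marginal and counted unstable
#' (this separates the genuine zero modes of the skew limit from
#' numerically tiny negatives).
#'
#' @param records data frame from [enumerate_equilibria()].
#' @param tol_eig eigenvalue tolerance.
#' @return The records with `stable` and `marginal` recomputed.
#' @export
stability <- function(records, tol_eig = 1e-8) {
  dom <- records$dominant_real
  records$marginal <- records$feasible & !is.na(dom) & abs(dom) <= tol_eig
  records$stable <- records$feasible & !is.na(dom) & dom < -tol_eig
  records
}

#' Shannon entropy of a frequency vector
#'
#' `H = -sum_{z_i > 0} z_i log z_i` (species evenness), with the convention
#' `0 * log 0 = 0`.  Bounded by `log(n)` on a support of size n, with
#' equality at the uniform distribution.
#'
#' @param z frequency vector on the simplex.
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4))  # log(4)
shannon_entropy <- function(z) {
  z <- z[z > 0]
  -sum(z * log(z))
}

#' Classify a system by its count of stable steady states
#'
#' @param records equilibrium records (after [stability()]).
#' @return List with `n_stable` and `category` in
#'   `{"no_stable", "monostable", "multistable"}`.
#' @export
classify_system <- function(records) {
  n_stable <- sum(records$stable)
  category <- if (n_stable == 0) "no_stable"
  else if (n_stable == 1) "monostable"
  else "multistable"
  list(n_stable = n_stable, category = category)
}

#' Strain overlap index between two supports
#'
#' Jaccard similarity `|A intersect B| / |A union B|` between the strain
#' sets of two steady states.
#'
#' @param support_a,support_b nonempty integer vectors of strain indices.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' strain_overlap_index(c(1, 2), c(2, 3))  # 1/3
strain_overlap_index <- function(support_a, support_b) {
  if (length(support_a) == 0 || length(support_b) == 0)
    stop("invalid input: supports must be nonempty")
  length(intersect(support_a, support_b)) /
    length(union(support_a, support_b))
}

#' Decode a support bitmask into strain indices
#'
#' @param mask integer bitmask as in [enumerate_equilibria()] records.
#' @param N strain pool size.
#' @return Integer vector of strain indices.
#' @export
support_from_mask <- function(mask, N) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1L))) != 0L)
}
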