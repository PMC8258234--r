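# Shared helpers for the test suite: small independent oracles and
# generators, kept free of the code paths they check.

# Finite-difference Jacobian of the replicator field (independent oracle
# for the analytic Jacobian used in stability analysis).
fd_replicator_jacobian <- function(z, Lambda, Theta = 1, h = 1e-7) {
  N <- length(z)
  J <- matrix(0, N, N)
  for (l in seq_len(N)) {
    zp <- z; zp[l] <- zp[l] + h
    zm <- z; zm[l] <- zm[l] - h
    J[, l] <- (replicator_rhs(zp, Lambda, Theta) -
                 replicator_rhs(zm, Lambda, Theta)) / (2 * h)
  }
  J
}

# Uniform random point in the interior of the simplex.
random_simplex <- function(N) {
  e <- -log(runif(N))
  e / sum(e)
}

# Brute-force orthant probability of opposite signs for a centered
# bivariate normal with correlation rho, by 2D Monte Carlo with antithetic
# pairs (independent of the closed form under test).
mc_exclusion_probability <- function(rho, n = 2e5) {
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  mean(sign(x) != sign(y))
}
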