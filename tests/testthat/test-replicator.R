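test_that("invasion fitness matrix follows the pairwise formula", {
  expect_equal(unclass(invasion_fitness_matrix(matrix(0, 3, 3), 2)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  L <- invasion_fitness_matrix(rbind(c(0, 1), c(-1, 0)), mu = 1)
  expect_equal(L[1, 2], -3)
  expect_equal(L[2, 1], 3)
  # mu = 0: invasion depends only on the resident's column of A
  A <- draw_normalized_matrix(5, seed = 11)
  L0 <- invasion_fitness_matrix(A, 0)
  for (j in 1:5) {
    col <- A[j, , drop = TRUE] - A[j, j]  # alpha_ji - alpha_jj over i
    col[j] <- 0
    expect_equal(L0[, j], col)
  }
  # diagonal structurally zero for any mu
  for (mu in c(0, 0.7, 13)) {
    expect_identical(diag(invasion_fitness_matrix(A, mu)), rep(0, 5))
  }
  # large-mu rescaled limit is skew-symmetric t(A) - A
  Lbig <- invasion_fitness_matrix(A, 1e8) / 1e8
  expect_equal(unclass(Lbig), t(unclass(A)) - unclass(A),
               tolerance = 1e-6, ignore_attr = TRUE)
  # lambda_ij + lambda_ji is mu-free: alpha_ij + alpha_ji - alpha_ii - alpha_jj
  for (mu in c(0, 1, 50)) {
    L <- invasion_fitness_matrix(A, mu)
    S <- L + t(L)
    expect_equal(S[1, 2], A[1, 2] + A[2, 1] - A[1, 1] - A[2, 2],
                 tolerance = 1e-12)
    expect_equal(S[3, 5], A[3, 5] + A[5, 3] - A[3, 3] - A[5, 5],
                 tolerance = 1e-12)
  }
  expect_error(invasion_fitness_matrix(A, -1), "invalid parameter")
})

test_that("pairwise outcomes classify by the signs of the two fitnesses", {
  expect_identical(classify_pair(2, 1), "coexistence")
  expect_identical(classify_pair(-1, -2), "bistability")
  expect_identical(classify_pair(1, -1), "exclusion_of_j")
  expect_identical(classify_pair(-1, 1), "exclusion_of_i")
  expect_identical(classify_pair(0, 5), "degenerate")
  expect_identical(classify_pair(c(1, -1, 0), c(1, 1, 1)),
                   c("coexistence", "exclusion_of_i", "degenerate"))
})

test_that("replicator field: hand value, vertices, and zero-sum property", {
  L <- rbind(c(0, 2), c(1, 0))
  expect_equal(replicator_rhs(c(0.5, 0.5), L)[1], 0.125)
  expect_equal(replicator_rhs(c(0.3, 0.7), rbind(c(0, 0), c(0, 0))),
               c(0, 0))
  set.seed(12)
  for (i in 1:20) {
    N <- sample(2:6, 1)
    Lr <- invasion_fitness_matrix(matrix(rnorm(N * N), N, N), runif(1, 0, 5))
    # vertices are equilibria
    for (j in seq_len(N)) {
      ej <- rep(0, N); ej[j] <- 1
      expect_equal(replicator_rhs(ej, Lr), rep(0, N), tolerance = 1e-14)
    }
    # components sum to zero on the simplex
    expect_equal(sum(replicator_rhs(random_simplex(N), Lr, Theta = 2.3)),
                 0, tolerance = 1e-13)
  }
})

test_that("two-strain coexistence converges to lambda12/(lambda12+lambda21)", {
  L <- rbind(c(0, 2), c(1, 0))
  tr <- integrate_replicator(c(0.9, 0.1), L, tau_max = 60)
  expect_equal(tr$z[nrow(tr$z), 1], 2 / 3, tolerance = 1e-6)
  # Lambda = 0: constant trajectory
  tr0 <- integrate_replicator(c(0.3, 0.7), matrix(0, 2, 2), tau_max = 10)
  expect_equal(tr0$z[nrow(tr0$z), ], c(0.3, 0.7), tolerance = 1e-10)
  # simplex preserved
  expect_lt(max(abs(rowSums(tr$z) - 1)), 1e-10)
})

test_that("community traits satisfy the selfishness identity q - Q = sum(alpha_ii z_i)", {
  set.seed(13)
  for (i in 1:100) {
    N <- sample(2:8, 1)
    A <- matrix(rnorm(N * N), N, N)
    mu <- runif(1, 0, 20)
    L <- invasion_fitness_matrix(A, mu)
    z <- random_simplex(N)
    tr <- community_traits(z, A, L)
    expect_lt(abs(tr$selfishness - sum(diag(A) * z)), 1e-12)
  }
  # vertex: q = alpha_11, Q = 0
  A <- draw_normalized_matrix(4, seed = 14)
  L <- invasion_fitness_matrix(A, 1.3)
  tr <- community_traits(c(1, 0, 0, 0), A, L)
  expect_equal(tr$q, A[1, 1])
  expect_equal(tr$Q, 0)
  # skew A (zero diagonal): selfishness vanishes
  S <- draw_normalized_matrix(5, seed = 15, structure = "skew")
  trS <- community_traits(random_simplex(5), S,
                          invasion_fitness_matrix(S, 2))
  expect_lt(abs(trS$selfishness), 1e-12)
})

test_that("skew-limit field is zero-sum and symmetric matrices freeze it", {
  set.seed(16)
  for (i in 1:20) {
    N <- sample(2:7, 1)
    A <- matrix(rnorm(N * N), N, N)
    z <- random_simplex(N)
    expect_equal(sum(rescaled_large_mu_rhs(z, A, 1.7)), 0,
                 tolerance = 1e-13)
    # the antisymmetric quadratic form vanishes identically
    S <- t(A) - A
    expect_equal(as.numeric(t(z) %*% S %*% z), 0, tolerance = 1e-12)
  }
  Asym <- matrix(rnorm(9), 3, 3); Asym <- Asym + t(Asym)
  expect_equal(rescaled_large_mu_rhs(random_simplex(3), Asym), rep(0, 3))
  # two-strain skew limit: neutral cycles, conserved interior distance
  A2 <- rbind(c(0, 1), c(0.2, 0))
  tr <- integrate_skew_limit(c(0.3, 0.7), A2, tau_max = 5)
  expect_lt(max(abs(rowSums(tr$z) - 1)), 1e-10)
})

test_that("reciprocal fitness correlation matches its closed form", {
  mu <- 1.5
  draws <- 1e4
  set.seed(17)
  a <- matrix(rnorm(4 * draws), draws, 4)
  l12 <- a[, 3] - a[, 4] - mu * (a[, 2] - a[, 3])
  l21 <- a[, 2] - a[, 1] - mu * (a[, 3] - a[, 2])
  rho_hat <- cor(l12, l21)
  rho <- lambda_pair_correlation(mu)
  se <- (1 - rho^2) / sqrt(draws)
  expect_lt(abs(rho_hat - rho), 3 * se)
  expect_equal(lambda_pair_correlation(0), 0)
  expect_equal(lambda_pair_correlation(5), -60 / 62)
})

test_that("attractor classification tracks the mu gradient of a cyclic system", {
  A <- make_rps_matrix()
  Af <- unclass(A); diag(Af) <- 1.2  # strong self-promotion: stable vertices
  L0 <- invasion_fitness_matrix(Af, 0)
  tr0 <- integrate_replicator(c(0.4, 0.35, 0.25), L0, tau_max = 300,
                              n_out = 3001)
  expect_identical(classify_attractor(tr0, L0), "fixed_point")
  L15 <- invasion_fitness_matrix(Af, 1.5)
  tr15 <- integrate_replicator(c(0.4, 0.35, 0.25), L15, tau_max = 300,
                               n_out = 3001)
  expect_identical(classify_attractor(tr15, L15), "heteroclinic_like")
  # zero-diagonal cyclic matrix at large mu: heteroclinic signature with
  # geometrically decreasing minima and recurrent near-monodominance
  L5 <- invasion_fitness_matrix(A, 5)
  tr5 <- integrate_replicator(c(0.4, 0.35, 0.25), L5, tau_max = 300,
                              n_out = 3001)
  expect_identical(classify_attractor(tr5, L5), "heteroclinic_like")
  last <- tr5$tau >= 150
  expect_gt(max(tr5$z[last, ]), 0.9)
  rm5 <- cummin(apply(tr5$z, 1, min))
  expect_lt(rm5[length(rm5)], rm5[which.max(tr5$tau > 150)] / 10)
  # stationary interior trajectory classifies as a fixed point
  Lc <- rbind(c(0, 2), c(1, 0))
  trc <- integrate_replicator(c(0.5, 0.5), Lc, tau_max = 80, n_out = 801)
  expect_identical(classify_attractor(trc, Lc), "fixed_point")
})
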