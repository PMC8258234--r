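test_that("two-strain enumeration finds vertices and the interior point", {
  L <- rbind(c(0, 2), c(1, 0))
  rec <- enumerate_equilibria(L)
  expect_equal(nrow(rec), 3L)
  expect_true(all(rec$feasible))
  interior <- rec[rec$n == 2, ]
  expect_equal(c(interior$z1, interior$z2), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_true(interior$stable)
  expect_false(any(rec$stable[rec$n == 1]))
  # negative lambda12: interior solution leaves the simplex
  rec2 <- enumerate_equilibria(rbind(c(0, -2), c(1, 0)))
  interior2 <- rec2[rec2$n == 2, ]
  expect_false(interior2$feasible)
  expect_equal(c(interior2$z1, interior2$z2), c(2, -1), tolerance = 1e-12)
  expect_true(all(rec2$feasible[rec2$n == 1]))
})

test_that("the neutral matrix yields a degenerate continuum beyond vertices", {
  rec <- enumerate_equilibria(matrix(0, 3, 3))
  expect_true(all(rec$feasible[rec$n == 1]))
  expect_true(all(rec$degenerate[rec$n > 1]))
  expect_false(any(rec$feasible[rec$n > 1]))
})

test_that("feasible equilibria zero the replicator field (residual oracle)", {
  set.seed(21)
  for (i in 1:30) {
    N <- sample(2:8, 1)
    L <- invasion_fitness_matrix(matrix(rnorm(N * N), N, N),
                                 runif(1, 0, 10))
    rec <- enumerate_equilibria(L, keep_infeasible = FALSE)
    zc <- as.matrix(rec[, paste0("z", 1:N)])
    for (r in seq_len(nrow(rec))) {
      res <- replicator_rhs(zc[r, ], L, Theta = 1)
      expect_lt(sqrt(sum(res^2)), 1e-9 * max(1, max(abs(L))))
    }
    # growth value equals the mean invasibility Q at the equilibrium
    for (r in which(rec$n > 1)) {
      Q <- as.numeric(t(zc[r, ]) %*% L %*% zc[r, ])
      expect_equal(rec$growth[r], Q, tolerance = 1e-9)
    }
  }
})

test_that("simplex-restricted Jacobian matches a finite-difference oracle
           and scales linearly in Theta", {
  set.seed(22)
  for (i in 1:10) {
    N <- sample(2:6, 1)
    L <- invasion_fitness_matrix(matrix(rnorm(N * N), N, N), runif(1, 0, 3))
    z <- random_simplex(N)
    sj <- simplex_jacobian(z, L, Theta = 1)
    expect_lt(max(abs(sj$jacobian - fd_replicator_jacobian(z, L))), 1e-5)
    sj2 <- simplex_jacobian(z, L, Theta = 2)
    expect_equal(sort(Re(sj2$spectrum)), sort(2 * Re(sj$spectrum)),
                 tolerance = 1e-9)
  }
  # interior coexistence of two mutual invaders is stable
  sj <- simplex_jacobian(c(2 / 3, 1 / 3), rbind(c(0, 2), c(1, 0)))
  expect_equal(length(sj$spectrum), 1L)
  expect_lt(Re(sj$spectrum[1]), 0)
  expect_equal(sj$dominant_real, -2 / 3, tolerance = 1e-12)
  # a vertex whose resident repels all invaders is locally stable
  A <- matrix(-abs(rnorm(16)), 4, 4); diag(A) <- 1
  L <- invasion_fitness_matrix(A, 0)  # lambda_ij = alpha_ji - alpha_jj < 0
  sj1 <- simplex_jacobian(c(1, 0, 0, 0), L)
  expect_lt(sj1$dominant_real, 0)
  # off-support directions carry the invasion rates
  inv_rates <- L[2:4, 1]
  expect_equal(sort(Re(sj1$spectrum)), sort(inv_rates), tolerance = 1e-9)
})

test_that("stability rule distinguishes stable, unstable and marginal", {
  rec <- data.frame(feasible = c(TRUE, TRUE, TRUE, FALSE),
                    dominant_real = c(-0.3, 0.01, 0, -1),
                    stable = NA, marginal = NA)
  out <- stability(rec, tol_eig = 1e-8)
  expect_identical(out$stable, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$marginal, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("long-run integration reaches only enumerated stable equilibria", {
  # brute-force oracle: random interior starts of small systems end at an
  # enumerated stable steady state whenever one exists
  set.seed(23)
  checked <- 0L
  for (i in 1:6) {
    N <- sample(3:4, 1)
    L <- invasion_fitness_matrix(matrix(rnorm(N * N), N, N), 0.2)
    rec <- stability(enumerate_equilibria(L, keep_infeasible = FALSE))
    st <- rec[rec$stable, , drop = FALSE]
    if (nrow(st) == 0) next
    zs <- as.matrix(st[, paste0("z", 1:N)])
    for (s in 1:20) {
      tr <- integrate_replicator(random_simplex(N), L, tau_max = 3000,
                                 n_out = 301)
      zT <- tr$z[nrow(tr$z), ]
      if (sqrt(sum(replicator_rhs(zT, L)^2)) > 1e-7) next  # cycling run
      d <- apply(zs, 1L, function(r) max(abs(r - zT)))
      expect_lt(min(d), 1e-5)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("entropy, system classification and overlap index behave", {
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  # entropy of enumerated equilibria respects the log(n) bound
  set.seed(24)
  L <- invasion_fitness_matrix(matrix(rnorm(64), 8, 8), 0.1)
  rec <- enumerate_equilibria(L, keep_infeasible = FALSE)
  expect_true(all(rec$entropy <= log(rec$n) + 1e-12))
  cls <- classify_system(stability(rec))
  expect_identical(cls$category,
                   c("no_stable", "monostable",
                     "multistable")[min(cls$n_stable, 2) + 1])
  expect_identical(classify_system(data.frame(stable = c(FALSE, FALSE)))$category,
                   "no_stable")
  expect_identical(classify_system(data.frame(stable = c(TRUE, FALSE)))$category,
                   "monostable")
  expect_identical(classify_system(data.frame(stable = rep(TRUE, 3)))$category,
                   "multistable")
  expect_equal(strain_overlap_index(c(1, 2), c(3, 4)), 0)
  expect_equal(strain_overlap_index(c(1, 2), c(1, 2)), 1)
  expect_equal(strain_overlap_index(c(1, 2), c(2, 3)), 1 / 3)
  expect_error(strain_overlap_index(integer(0), 1), "invalid input")
  expect_identical(support_from_mask(5L, 4), c(1L, 3L))
})
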