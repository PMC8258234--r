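test_that("pairwise outcome fractions track the orthant closed form", {
  # the analytic curve itself against an independent Monte-Carlo orthant
  set.seed(31)
  for (mu in c(0.25, 2)) {
    rho <- lambda_pair_correlation(mu)
    p_mc <- mc_exclusion_probability(rho)
    expect_lt(abs(p_mc - pairwise_outcome_probabilities(mu)$exclusion),
              3 * sqrt(0.25 / 2e5) + 3e-3)
  }
  # simulated block fractions against the closed form at several mu
  for (mu in c(0, 0.25, 0.5, 1, 2, 5, 10)) {
    pf <- pairwise_outcome_fractions(mu, n_pairs = 10000, seed = 1)
    se <- sqrt(0.25 / 10000)
    expect_lt(abs(pf$fractions[["exclusion"]] - pf$analytic$exclusion),
              3 * se)
    expect_equal(sum(pf$fractions), 1, tolerance = 1e-12)
  }
  # at mu = 0 the four outcomes are equiprobable (exclusion counts two)
  p0 <- pairwise_outcome_probabilities(0)
  expect_equal(p0$exclusion, 0.5)
  expect_equal(p0$coexistence, 0.25)
  expect_equal(p0$bistability, 0.25)
  # determinism by seed
  expect_identical(pairwise_outcome_fractions(1, 2000, seed = 4)$fractions,
                   pairwise_outcome_fractions(1, 2000, seed = 4)$fractions)
})

test_that("regime fractions partition and shift with mu as expected", {
  rs <- regime_scan(c(0.05, 5), N = 6, n_systems = 300, seed = 2)
  fr <- rs$regimes
  expect_equal(fr$fraction_no_stable + fr$fraction_monostable +
                 fr$fraction_multistable, rep(1, 2), tolerance = 1e-12)
  # multistability common at small mu, rare at large; no-stable the reverse
  expect_gt(fr$fraction_multistable[1], fr$fraction_multistable[2])
  expect_lt(fr$fraction_no_stable[1], fr$fraction_no_stable[2])
  d <- rs$stable_count_distribution
  expect_equal(sum(d$fraction[d$mu == 0.05]), 1, tolerance = 1e-12)
})

test_that("no two stable steady states share a support (pure multistability
           is impossible)", {
  set.seed(33)
  for (i in 1:40) {
    N <- sample(4:8, 1)
    L <- invasion_fitness_matrix(matrix(rnorm(N * N), N, N),
                                 runif(1, 0, 2))
    rec <- enumerate_equilibria(L, keep_infeasible = FALSE)
    st <- rec$support[rec$stable]
    expect_identical(anyDuplicated(st), 0L)
  }
})

test_that("diversity-stability pooling obeys entropy bounds and evenness
           raises stability within a support size", {
  d <- diversity_stability_experiment(N = 6, mu = 0.05, n_systems = 300,
                                      seed = 3, entropy_bins = 10)
  expect_true(all(d$records$entropy <= log(d$records$n) + 1e-12))
  expect_gt(d$share_stable, 0)
  expect_lt(d$share_stable, 0.3)
  # within n = 3: stability magnitude of stable states increases with
  # entropy (rank correlation of binned means positive)
  cv <- d$curves[d$curves$n == 3 & !is.na(d$curves$s), ]
  if (nrow(cv) >= 3)
    expect_gt(cor(cv$entropy_mid, cv$s, method = "spearman"), 0)
  # rank profiles are decreasing frequency vectors on their support
  for (prof in d$rank_profiles) {
    if (is.null(prof)) next
    expect_true(all(diff(prof) <= 1e-12))
    expect_equal(sum(prof), 1, tolerance = 1e-6)
  }
})

test_that("overlap statistics: stable-only SOI below all-pairs SOI, both in [0,1]", {
  s <- soi_experiment(mu = 0.05, N = 6, n_systems = 300, seed = 5)
  expect_gte(s$mean_soi_all, 0); expect_lte(s$mean_soi_all, 1)
  expect_gte(s$mean_soi_stable, 0); expect_lte(s$mean_soi_stable, 1)
  expect_lt(s$mean_soi_stable, s$mean_soi_all)
  nv <- nonoverlap_multistability_probability(0.05, N = 6, n_systems = 200,
                                              seed = 6)
  expect_gte(nv$fraction, 0); expect_lte(nv$fraction, 1)
})

test_that("skew-limit coexistence counts are odd-only and follow the
           combinatorial law", {
  cc <- coexistence_count_distribution(N = 3, n_systems = 4000, seed = 7,
                                       skew_limit = TRUE)
  expect_equal(cc$distribution[["2"]], 0)
  se1 <- sqrt(0.75 * 0.25 / 4000)
  expect_lt(abs(cc$distribution[["1"]] - 0.75), 3 * se1)
  expect_lt(abs(cc$distribution[["3"]] - 0.25), 3 * se1)
  cc5 <- coexistence_count_distribution(N = 5, n_systems = 2000, seed = 8,
                                        skew_limit = TRUE)
  expect_true(all(cc5$distribution[c("2", "4")] == 0))
  for (k in c(1, 3, 5)) {
    p <- choose(5, k) * 2^(1 - 5)
    expect_lt(abs(cc5$distribution[[as.character(k)]] - p),
              3 * sqrt(p * (1 - p) / 2000))
  }
  # mean number of coexisting strains grows along the mu gradient
  ms <- vapply(c(0.1, 1, 10), function(mu)
    coexistence_count_distribution(N = 8, n_systems = 250, seed = 9,
                                   mu = mu)$mean_n, 0)
  expect_true(all(diff(ms) > 0))
})

test_that("full-support feasibility at mu = 0 follows the orthant-branch laws", {
  for (n in c(2, 3)) {
    f <- feasibility_probability_experiment(n, n_systems = 4000, seed = 10)
    expect_lt(abs(f$fraction_positive_growth - 2^(-n)),
              3 * f$se_positive_growth + 1e-12)
    expect_lt(abs(f$fraction_feasible - 2^(1 - n)),
              3 * f$se_feasible + 1e-12)
  }
  f1 <- feasibility_probability_experiment(1, n_systems = 10, seed = 11)
  expect_equal(f1$fraction_feasible, 1)
})
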