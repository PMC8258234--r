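# Monte-Carlo ensemble experiments over random interaction matrices.
#
# All generators below are pure functions of their (seed, n_systems, mu, N)
# arguments; matrices are drawn sequentially under a single seeded RNG
# stream so reruns are bit-identical.

# Iterate over an ensemble of random systems, calling `fn(raw, A)` on the
# feasible-equilibrium records of each (raw is the list returned by the
# compiled enumerator, feasible rows only).
ensemble_apply <- function(N, mu, n_systems, seed, fn,
                           structure = "iid_normal", want_z = FALSE,
                           tol_feas = 1e-9, cond_tol = 1e12,
                           tol_eig = 1e-8, skew_limit = FALSE) {
  if (n_systems < 1) stop("n_systems must be at least 1")
  with_seed(seed, {
    res <- vector("list", n_systems)
    for (s in seq_len(n_systems)) {
      A <- matrix(rnorm(N * N), N, N)
      if (structure == "zero_diagonal") diag(A) <- 0
      if (structure == "skew") A <- (A - t(A)) / sqrt(2)
      if (skew_limit) {
        L <- t(A) - A
      } else {
        L <- t(A) - matrix(diag(A), N, N, byrow = TRUE) - mu * (A - t(A))
        diag(L) <- 0
      }
      raw <- enum_equilibria_cpp(L, tol_feas, cond_tol, tol_eig,
                                 FALSE, want_z)
      res[[s]] <- fn(raw, A)
    }
    res
  })
}

# Bit-count lookup table for support masks of an N-strain pool.
popcount_table <- function(N) {
  masks <- 0:(2^N - 1)
  counts <- integer(length(masks))
  m <- masks
  while (any(m > 0)) {
    counts <- counts + (m %% 2L)
    m <- m %/% 2L
  }
  counts
}

#' Correlation between reciprocal pairwise invasion fitnesses
#'
#' For i.i.d. standard-normal interaction entries, `lambda_ij` and
#' `lambda_ji` are jointly normal with correlation
#' `rho(mu) = -2 mu (1 + mu) / ((1 + mu)^2 + mu^2 + 1)`, which tends to -1
#' as `mu` grows -- the mechanism pushing random pairs towards competitive
#' exclusion.
#'
#' @param mu single-to-co-colonization ratio.
#' @return Correlation in `(-1, 0]`.
#' @export
lambda_pair_correlation <- function(mu) {
  -2 * mu * (1 + mu) / ((1 + mu)^2 + mu^2 + 1)
}

#' Analytic pairwise-outcome probabilities under random interactions
#'
#' Closed-form orthant probabilities for a centered bivariate normal pair
#' `(lambda_ij, lambda_ji)` with correlation `rho(mu)`: exclusion (opposite
#' signs) has probability `1/2 - asin(rho)/pi`; coexistence and bistability
#' each have probability `1/4 + asin(rho)/(2 pi)`.
#'
#' @param mu single-to-co-colonization ratio.
#' @return List with `exclusion`, `coexistence`, `bistability`, `rho`.
#' @export
#' @examples
#' pairwise_outcome_probabilities(0)$exclusion  # exactly 1/2
pairwise_outcome_probabilities <- function(mu) {
  rho <- lambda_pair_correlation(mu)
  list(exclusion = 0.5 - asin(rho) / pi,
       coexistence = 0.25 + asin(rho) / (2 * pi),
       bistability = 0.25 + asin(rho) / (2 * pi),
       rho = rho)
}

#' Pairwise-outcome fractions from random 2 x 2 interaction blocks
#'
#' Draws `n_pairs` independent 2 x 2 blocks with entries i.i.d. N(0,1)
#' (all four entries drawn, diagonal included), builds the two invasion
#' fitnesses at the given `mu`, classifies each pair, and returns the
#' empirical outcome fractions next to the analytic orthant prediction.
#'
#' @param mu single-to-co-colonization ratio.
#' @param n_pairs number of random pairs (>= 1000 recommended).
#' @param seed RNG seed.
#' @return List with `fractions` (named: coexistence, bistability,
#'   exclusion, degenerate), `analytic`, `se_exclusion` (binomial standard
#'   error), `n_pairs`, `mu`, `seed`.
#' @export
pairwise_outcome_fractions <- function(mu, n_pairs = 10000L, seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  draws <- with_seed(seed, matrix(rnorm(4 * n_pairs), n_pairs, 4))
  a11 <- draws[, 1L]; a12 <- draws[, 2L]
  a21 <- draws[, 3L]; a22 <- draws[, 4L]
  l12 <- a21 - a22 - mu * (a12 - a21)
  l21 <- a12 - a11 - mu * (a21 - a12)
  cls <- classify_pair(l12, l21)
  excl <- cls %in% c("exclusion_of_i", "exclusion_of_j")
  fr <- c(coexistence = mean(cls == "coexistence"),
          bistability = mean(cls == "bistability"),
          exclusion = mean(excl),
          degenerate = mean(cls == "degenerate"))
  p <- fr[["exclusion"]]
  list(fractions = fr,
       analytic = pairwise_outcome_probabilities(mu),
       se_exclusion = sqrt(p * (1 - p) / n_pairs),
       n_pairs = n_pairs, mu = mu, seed = seed)
}

#' Dynamic-regime fractions across a mu grid
#'
#' For each `mu`, generates `n_systems` random N-strain systems, enumerates
#' and classifies their steady states, and reports the proportion of
#' systems with no stable steady state, exactly one (monostable), or
#' several (multistable), with binomial standard errors.  Matrices are
#' redrawn independently per `mu` value.
#'
#' @param mu_grid vector of mu values.
#' @param N strain pool size.
#' @param n_systems replicates per mu.
#' @param seed master seed; per-mu sub-seeds are derived from it.
#' @return List with `regimes` (data frame: one row per mu) and
#'   `stable_count_distribution` (data frame of fractions of systems with
#'   0..6+ stable states per mu).
#' @export
regime_scan <- function(mu_grid, N = 10L, n_systems = 1000L, seed = 1L) {
  rows <- vector("list", length(mu_grid))
  dist_rows <- vector("list", length(mu_grid))
  for (mi in seq_along(mu_grid)) {
    mu <- mu_grid[mi]
    counts <- unlist(ensemble_apply(N, mu, n_systems, derive_seed(seed, mi),
                                    function(raw, A) sum(raw$stable)))
    fr <- c(no_stable = mean(counts == 0),
            monostable = mean(counts == 1),
            multistable = mean(counts >= 2))
    se <- sqrt(fr * (1 - fr) / n_systems)
    rows[[mi]] <- data.frame(mu = mu,
                             fraction_no_stable = fr[["no_stable"]],
                             fraction_monostable = fr[["monostable"]],
                             fraction_multistable = fr[["multistable"]],
                             se_no_stable = se[["no_stable"]],
                             se_monostable = se[["monostable"]],
                             se_multistable = se[["multistable"]],
                             n_systems = n_systems)
    capped <- pmin(counts, 6L)
    dist_rows[[mi]] <- data.frame(mu = mu, n_stable = 0:6,
                                  fraction = as.vector(
                                    tabulate(capped + 1L, 7L) / n_systems))
  }
  list(regimes = do.call(rbind, rows),
       stable_count_distribution = do.call(rbind, dist_rows))
}

#' Diversity-stability experiment at fixed mu
#'
#' Pools all feasible steady states across random systems and stratifies
#' them by number of coexisting strains `n` and Shannon-entropy bin.  For
#' each stratum it reports the proportion of steady states that are stable
#' `f(E)`, the mean stability magnitude `s(E) = mean |dominant eigenvalue|`
#' among stable ones, and the effective stability `f(E) * s(E)`.  Also
#' returns, per `n`, the mean rank-ordered frequency profile of stable
#' states in the bin where effective stability peaks ("optimal intermediate
#' evenness").
#'
#' @param N strain pool size.
#' @param mu single-to-co-colonization ratio.
#' @param n_systems ensemble size.
#' @param seed RNG seed.
#' @param entropy_bins number of equal-width entropy bins on `[0, log N]`.
#' @return List with `records` (pooled per-equilibrium data frame),
#'   `curves` (per n x bin strata), `rank_profiles`, `share_stable` (the
#'   overall proportion of feasible steady states that are stable), and the
#'   parameters.
#' @export
diversity_stability_experiment <- function(N = 10L, mu = 0.05,
                                           n_systems = 2000L, seed = 1L,
                                           entropy_bins = 20L) {
  if (entropy_bins < 5) stop("entropy_bins must be at least 5")
  acc <- ensemble_apply(N, mu, n_systems, seed, want_z = TRUE,
                        fn = function(raw, A) {
    keep <- raw$feasible
    zst <- t(raw$z)[keep & raw$stable, , drop = FALSE]
    list(n = raw$n[keep], entropy = raw$entropy[keep],
         dom = raw$dominant_real[keep], stable = raw$stable[keep],
         z_stable = zst)
  })
  records <- data.frame(
    system = rep(seq_along(acc), vapply(acc, function(a) length(a$n), 1L)),
    n = unlist(lapply(acc, `[[`, "n")),
    entropy = unlist(lapply(acc, `[[`, "entropy")),
    dominant_real = unlist(lapply(acc, `[[`, "dom")),
    stable = unlist(lapply(acc, `[[`, "stable")))
  z_stable <- do.call(rbind, lapply(acc, `[[`, "z_stable"))
  breaks <- seq(0, log(N), length.out = entropy_bins + 1L)
  bin <- pmin(pmax(findInterval(records$entropy, breaks,
                                rightmost.closed = TRUE), 1L), entropy_bins)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  curves <- do.call(rbind, lapply(sort(unique(records$n)), function(nn) {
    sel <- records$n == nn
    do.call(rbind, lapply(seq_len(entropy_bins), function(b) {
      s2 <- sel & bin == b
      if (!any(s2)) return(NULL)
      f <- mean(records$stable[s2])
      stab <- s2 & records$stable
      s_mag <- if (any(stab)) mean(abs(records$dominant_real[stab])) else NA
      data.frame(n = nn, bin = b, entropy_mid = mids[b],
                 n_states = sum(s2), f = f, s = s_mag,
                 effective_stability = ifelse(is.na(s_mag), NA, f * s_mag))
    }))
  }))
  stable_bin <- bin[records$stable]
  stable_n <- records$n[records$stable]
  rank_profiles <- lapply(setNames(nm = sort(unique(stable_n))),
                          function(nn) {
    cv <- curves[curves$n == nn & !is.na(curves$effective_stability), ,
                 drop = FALSE]
    if (nrow(cv) == 0) return(NULL)
    b_opt <- cv$bin[which.max(cv$effective_stability)]
    zz <- z_stable[stable_n == nn & stable_bin == b_opt, , drop = FALSE]
    prof <- colMeans(t(apply(zz, 1L, sort, decreasing = TRUE)))
    prof[seq_len(nn)]
  })
  list(records = records, curves = curves, rank_profiles = rank_profiles,
       share_stable = mean(records$stable),
       params = list(N = N, mu = mu, n_systems = n_systems, seed = seed,
                     entropy_bins = entropy_bins))
}

#' Strain-overlap index experiment
#'
#' Within each random system, averages the Jaccard strain-overlap index
#' over all unordered pairs of feasible steady states, and separately over
#' pairs of stable steady states; then averages across systems.  Systems
#' with fewer than two steady states (resp. stable states) are excluded
#' from the corresponding average.
#'
#' @param mu single-to-co-colonization ratio.
#' @param N strain pool size.
#' @param n_systems ensemble size.
#' @param seed RNG seed.
#' @return List with `mean_soi_all`, `mean_soi_stable`, the per-system
#'   values, and counts of contributing systems.
#' @export
soi_experiment <- function(mu = 0, N = 10L, n_systems = 2000L, seed = 1L) {
  pc <- popcount_table(N)
  mean_soi <- function(masks) {
    K <- length(masks)
    if (K < 2L) return(NA_real_)
    pr <- combn(K, 2L)
    a <- masks[pr[1L, ]]
    b <- masks[pr[2L, ]]
    mean(pc[bitwAnd(a, b) + 1L] / pc[bitwOr(a, b) + 1L])
  }
  acc <- ensemble_apply(N, mu, n_systems, seed, function(raw, A) {
    m <- raw$support[raw$feasible]
    ms <- raw$support[raw$stable]
    c(all = mean_soi(m), stable = mean_soi(ms))
  })
  soi_all <- vapply(acc, `[[`, 0, "all")
  soi_stable <- vapply(acc, `[[`, 0, "stable")
  list(mean_soi_all = mean(soi_all, na.rm = TRUE),
       mean_soi_stable = mean(soi_stable, na.rm = TRUE),
       soi_all = soi_all, soi_stable = soi_stable,
       n_systems_all = sum(!is.na(soi_all)),
       n_systems_stable = sum(!is.na(soi_stable)),
       params = list(mu = mu, N = N, n_systems = n_systems, seed = seed))
}

#' Probability of multistability with disjoint strain subsets
#'
#' Fraction of random systems possessing at least two stable steady states
#' whose supports are disjoint (community composition then depends entirely
#' on initial conditions / founder effects).
#'
#' @inheritParams soi_experiment
#' @return List with `fraction`, `se` (binomial), and parameters.
#' @export
nonoverlap_multistability_probability <- function(mu, N = 10L,
                                                  n_systems = 1000L,
                                                  seed = 1L) {
  hits <- unlist(ensemble_apply(N, mu, n_systems, seed, function(raw, A) {
    ms <- raw$support[raw$stable]
    if (length(ms) < 2L) return(FALSE)
    pr <- combn(length(ms), 2L)
    any(bitwAnd(ms[pr[1L, ]], ms[pr[2L, ]]) == 0L)
  }))
  p <- mean(hits)
  list(fraction = p, se = sqrt(p * (1 - p) / n_systems),
       params = list(mu = mu, N = N, n_systems = n_systems, seed = seed))
}

#' Distribution of the number of coexisting strains
#'
#' In the skew (single-colonization) limit the attractor support is the
#' unique saturated feasible equilibrium of the zero-sum replicator; only
#' odd support sizes occur, with the combinatorial law
#' `P(n = k) = choose(N, k) * 2^(1 - N)` for odd k.  At finite `mu`, the
#' support sizes of stable steady states are pooled across systems instead.
#'
#' @param N strain pool size.
#' @param n_systems ensemble size.
#' @param seed RNG seed.
#' @param mu finite ratio (ignored when `skew_limit = TRUE`).
#' @param skew_limit use the rescaled skew-symmetric dynamics `t(A) - A`
#'   with skew-structured matrices.
#' @return List with `distribution` (fractions over n = 1..N), `mean_n`,
#'   `analytic` (skew law, when applicable), `counts`, and parameters.
#' @export
coexistence_count_distribution <- function(N = 10L, n_systems = 1000L,
                                           seed = 1L, mu = NULL,
                                           skew_limit = FALSE) {
  if (skew_limit) {
    ns <- unlist(ensemble_apply(N, mu = 0, n_systems, seed,
                                structure = "skew", skew_limit = TRUE,
                                fn = function(raw, A) {
      sat <- raw$feasible & raw$max_invasion < 0
      if (!any(sat)) return(NA_integer_)
      raw$n[sat][which.min(raw$max_invasion[sat])]
    }))
    ns <- ns[!is.na(ns)]
    analytic <- ifelse(seq_len(N) %% 2L == 1L,
                       choose(N, seq_len(N)) * 2^(1 - N), 0)
    names(analytic) <- seq_len(N)
  } else {
    if (is.null(mu)) stop("mu must be given when skew_limit = FALSE")
    ns <- unlist(ensemble_apply(N, mu, n_systems, seed,
                                fn = function(raw, A) raw$n[raw$stable]))
    analytic <- NULL
  }
  distribution <- tabulate(ns, N) / max(length(ns), 1L)
  names(distribution) <- seq_len(N)
  list(distribution = distribution, mean_n = mean(ns), counts = ns,
       analytic = analytic,
       params = list(N = N, n_systems = n_systems, seed = seed, mu = mu,
                     skew_limit = skew_limit))
}

#' Feasibility probability of the full-support equilibrium at mu = 0
#'
#' With zero-diagonal interactions and `mu = 0` the invasion matrix is
#' `t(A)` and the replicator maps onto generalized Lotka-Volterra dynamics
#' with equal growth rates.  The cited combinatorial law -- a feasible
#' positive steady state with probability exactly `2^(-n)` -- counts the
#' positive-growth solution branch (common growth `c > 0`).  Because the
#' replicator normalizes frequencies, the mirrored all-negative branch also
#' yields a simplex equilibrium, so the probability that the full-support
#' replicator equilibrium is feasible is `2^(1 - n)`.  Both fractions are
#' returned.
#'
#' @param n number of strains.
#' @param n_systems ensemble size.
#' @param seed RNG seed.
#' @return List with `fraction_positive_growth` (compare to `2^-n`),
#'   `fraction_feasible` (compare to `2^(1-n)`), standard errors, analytic
#'   references, and parameters.
#' @export
feasibility_probability_experiment <- function(n, n_systems = 10000L,
                                               seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  res <- with_seed(seed, {
    out <- matrix(NA, n_systems, 2L)
    for (s in seq_len(n_systems)) {
      A <- matrix(rnorm(n * n), n, n)
      diag(A) <- 0
      if (n == 1L) {
        out[s, ] <- c(TRUE, FALSE)  # vertex feasible; growth c = 0
        next
      }
      L <- t(A)
      M <- rbind(cbind(L, rep(-1, n)), c(rep(1, n), 0))
      x <- tryCatch(solve(M, c(rep(0, n), 1)), error = function(e) NULL)
      if (is.null(x)) next
      feas <- all(x[seq_len(n)] > 1e-9)
      out[s, ] <- c(feas, feas && x[n + 1L] > 0)
    }
    out
  })
  p_feas <- mean(res[, 1L], na.rm = TRUE)
  p_pos <- mean(res[, 2L], na.rm = TRUE)
  list(fraction_feasible = p_feas,
       fraction_positive_growth = p_pos,
       se_feasible = sqrt(p_feas * (1 - p_feas) / n_systems),
       se_positive_growth = sqrt(p_pos * (1 - p_pos) / n_systems),
       analytic_positive_growth = if (n == 1L) NA_real_ else 2^(-n),
       analytic_feasible = if (n == 1L) 1 else 2^(1 - n),
       params = list(n = n, n_systems = n_systems, seed = seed))
}
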