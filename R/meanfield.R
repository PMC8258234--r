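#' Single-to-co-colonization ratio
#'
#' The ratio `mu = I/D` of endemic single-colonization to co-colonization
#' prevalence, which in this model has the closed form
#' `mu = 1 / ((R0 - 1) * k)`.  It is the key gradient tuning pairwise
#' invasion asymmetry and hence the complexity of multi-strain dynamics.
#'
#' @param R0 basic reproduction number `beta/m`, must exceed 1.
#' @param k mean interaction coefficient in co-colonization, positive.
#' @return The dimensionless ratio `mu`.
#' @export
#' @examples
#' single_to_cocolonization_ratio(R0 = 2, k = 0.1)  # 10
single_to_cocolonization_ratio <- function(R0, k) {
  if (any(R0 <= 1)) stop("no endemic state: R0 must exceed 1")
  if (any(k <= 0)) stop("invalid parameter: k must be positive")
  1 / ((R0 - 1) * k)
}

#' Conserved endemic prevalences of the neutral system
#'
#' On the fast timescale the system settles on the neutral endemic state
#' where total prevalences are conserved: susceptibles `S = 1/R0`, total
#' single colonization `I = (R0-1) / (R0 * (1 + k*(R0-1)))`, and total
#' co-colonization `D = k*(R0-1)*I`.  They sum to 1 and satisfy `I/D = mu`.
#'
#' @inheritParams single_to_cocolonization_ratio
#' @return A list with components `S`, `I`, `D`.
#' @export
#' @examples
#' conserved_prevalences(R0 = 2, k = 1)  # S = 0.5, I = 0.25, D = 0.25
conserved_prevalences <- function(R0, k) {
  if (any(R0 <= 1)) stop("no endemic state: R0 must exceed 1")
  if (any(k <= 0)) stop("invalid parameter: k must be positive")
  S <- 1 / R0
  I <- (R0 - 1) / (R0 * (1 + k * (R0 - 1)))
  D <- k * (R0 - 1) * I
  list(S = S, I = I, D = D)
}

#' Selection speed of the slow dynamics
#'
#' The rate `Theta` multiplying the replicator vector field on the slow
#' timescale.  Two algebraically equivalent closed forms are evaluated --
#' the mu-form `Theta = beta*(1 - 1/R0)*mu / (2*(mu+1)^2 - mu)` and the
#' prevalence form `Theta = beta*(1-S)*I*D / (2*(1-S)^2 - I*D)` -- and
#' cross-checked to 1e-12 relative tolerance before returning.  In the
#' strong-facilitation limit `k -> Inf`, `Theta -> m/(2k)`; in the
#' strong-competition limit `k -> 0`, `mu*Theta -> m*(R0-1)/2`.
#'
#' @param beta transmission rate (per unit time).
#' @param m infected-host turnover rate (per unit time).
#' @param k mean interaction coefficient, positive.
#' @return The selection speed `Theta` (per slow-time unit), positive.
#' @export
#' @examples
#' selection_speed(beta = 2, m = 1, k = 1)  # 1/7
selection_speed <- function(beta, m, k) {
  if (any(beta <= 0) || any(m <= 0)) stop("beta and m must be positive")
  R0 <- beta / m
  if (any(R0 <= 1)) stop("no endemic state: R0 = beta/m must exceed 1")
  if (any(k <= 0)) stop("invalid parameter: k must be positive")
  mu <- single_to_cocolonization_ratio(R0, k)
  th1 <- beta * (1 - 1 / R0) * mu / (2 * (mu + 1)^2 - mu)
  p <- conserved_prevalences(R0, k)
  th2 <- beta * (1 - p$S) * p$I * p$D / (2 * (1 - p$S)^2 - p$I * p$D)
  if (any(abs(th1 - th2) > 1e-12 * pmax(abs(th1), abs(th2))))
    stop("internal inconsistency between the two Theta closed forms")
  th1
}

#' Mean-field context of an endemic multi-strain system
#'
#' Bundles the conserved prevalences, the single-to-co-colonization ratio
#' and the selection speed for a given parameter set.
#'
#' @inheritParams selection_speed
#' @return A list with components `S`, `I`, `D`, `mu`, `theta`, `R0`,
#'   `beta`, `m`, `k`.
#' @export
mean_field_context <- function(beta, m, k) {
  R0 <- beta / m
  p <- conserved_prevalences(R0, k)
  ctx <- c(p, list(mu = single_to_cocolonization_ratio(R0, k),
                   theta = selection_speed(beta, m, k),
                   R0 = R0, beta = beta, m = m, k = k))
  stopifnot(abs(ctx$S + ctx$I + ctx$D - 1) < 1e-12,
            abs(ctx$I / ctx$D - ctx$mu) < 1e-12 * ctx$mu)
  ctx
}

#' Mean-interaction coefficient tracing a fixed coexistence regime
#'
#' For a fixed ratio `mu0` the basic reproduction number and the mean
#' interaction coefficient trade off against each other:
#' `k(R0) = 1 / ((R0 - 1) * mu0)`.  Along this curve the qualitative
#' multi-strain dynamics are preserved while the environment (transmission
#' intensity) changes -- harsher environments demand more facilitation, the
#' model's expression of the stress-gradient hypothesis.
#'
#' @param R0 basic reproduction number(s) > 1.
#' @param mu0 the ratio to hold fixed, positive.
#' @return `k` value(s) such that
#'   `single_to_cocolonization_ratio(R0, k) == mu0`.
#' @export
tradeoff_k_for_mu <- function(R0, mu0) {
  if (any(R0 <= 1)) stop("no endemic state: R0 must exceed 1")
  if (any(mu0 <= 0)) stop("mu0 must be positive")
  1 / ((R0 - 1) * mu0)
}
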