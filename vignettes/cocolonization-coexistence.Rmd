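---
title: "Methods: multi-strain SIS co-colonization and the replicator reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-strain SIS co-colonization and the replicator reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straincoex)
```

## The model

`straincoex` studies an endemic SIS (susceptible–infected–susceptible)
system of $N$ closely related strains whose only fitness differences arise
through *altered susceptibilities to co-colonization*: a host already
colonized by strain $i$ acquires strain $j$ at a rate modified by the
factor $K_{ij}$ ($K_{ij} > 1$: facilitation, $K_{ij} < 1$:
inhibition/competition). The host compartments are susceptibles $S$,
singly colonized $I_i$, and ordered co-colonization classes $I_{ij}$
(first $i$, then $j$; $I_{ii}$ allowed). With force of infection
$F_i = \beta\,(I_i + \sum_j \tfrac12 (I_{ij} + I_{ji}))$ and infected-host
turnover $m = \gamma + r$ (clearance plus balanced host renewal):

$$
\dot S = m(1-S) - S\sum_j F_j,\qquad
\dot I_i = F_i S - m I_i - I_i \sum_j K_{ij} F_j,\qquad
\dot I_{ij} = I_i K_{ij} F_j - m I_{ij}.
$$

Total host mass obeys $\dot T = m(1-T)$ exactly, so trajectories started
at $T=1$ conserve it; `integrate_full()` enforces this to $10^{-8}$.

The interaction matrix is decomposed around the community mean,
$K_{ij} = k + \varepsilon\,\alpha_{ij}$, where $k$ is the mean interaction
coefficient, $0 < \varepsilon \ll 1$ the deviation scale, and
$A = (\alpha_{ij})$ the *normalized interaction matrix* (mean $\approx 0$,
variance $\approx 1$ in the unpruned pool). In the random ensembles the
$\alpha_{ij}$ are drawn i.i.d. standard normal, with no per-matrix
re-centering — each sample keeps its sampling fluctuations, as a finite
random community would.

## The slow-timescale reduction

For small $\varepsilon$ the dynamics separate into a fast neutral phase
and a slow selective phase. On the fast timescale ($\varepsilon = 0$) all
strains are exchangeable and the system relaxes onto the neutral endemic
manifold with conserved global prevalences

$$
S = \frac{1}{R_0},\qquad
I = \frac{R_0 - 1}{R_0\,(1 + k(R_0-1))},\qquad
D = k (R_0 - 1)\, I, \qquad S + I + D = 1,
$$

where $R_0 = \beta/m$. On the slow timescale $\tau = \varepsilon t$ the
strain frequencies $z_i$ obey an $N$-dimensional replicator equation

$$
\frac{dz_i}{d\tau} = \Theta\, z_i\!\left((\Lambda z)_i - Q(z)\right),
\qquad Q(z) = z^\top \Lambda z,
$$

with pairwise invasion fitnesses

$$
\lambda_{ij} = \alpha_{ji} - \alpha_{jj} - \mu\,(\alpha_{ij} -
\alpha_{ji}),
\qquad
\mu = \frac{I}{D} = \frac{1}{(R_0-1)\,k}.
$$

$\mu$, the **single-to-co-colonization ratio**, is the model's key
gradient: it weighs the asymmetry term $\alpha_{ij}-\alpha_{ji}$ in every
pairwise comparison. The selection speed has the closed form
$\Theta = \beta(1 - 1/R_0)\,\mu / (2(\mu+1)^2 - \mu)$, equivalently
$\beta(1-S)ID/(2(1-S)^2 - ID)$. The printed source formulas for $\Theta$
reached us garbled, so `selection_speed()` evaluates *both*
reconstructions and refuses to return unless they agree to $10^{-12}$
relative; the two asymptotic anchors $\Theta \to m/(2k)$ (as
$k \to \infty$) and $\mu\Theta \to m(R_0-1)/2$ (as $k \to 0$) are enforced
in the test suite, so a mis-reconstruction cannot pass silently. The
relative deviation of $\Theta$ from $m/(2k)$ is $\approx \tfrac32\mu$, so
the 1%-level check uses $k = 200$ ($\mu = 0.005$).

On the slow manifold the frequencies read out identically from single and
co-colonization ($z_i = I_i/I = D_i/D$), and the full state is
reconstructed as $I_i = I z_i$, $I_{ij} = D z_i z_j$.
`validate_reduction()` integrates both models from a common slow-manifold
start and reports the sup-norm discrepancy; halving $\varepsilon$ halves
it (measured ratios $\approx 1.96$–$1.98$ at
$\varepsilon \in \{0.1, 0.05, 0.025\}$), the first-order signature of the
timescale separation.

## Numerical choices

* **Replicator integration is done in log-frequency coordinates**
  $u_i = \log z_i$, $\dot u_i = \Theta((\Lambda z)_i - Q)$. Linear-space
  integration loses positivity near the simplex boundary and explodes on
  heteroclinic approaches; log coordinates keep boundary faces exactly
  invariant, never floor small frequencies (excursions to $\sim 10^{-300}$
  rebound correctly), and let `lsoda` take large steps. Frequencies are
  renormalized at output times (simplex preserved to $10^{-10}$); strains
  starting at exactly zero stay on their face, as in the exact dynamics.
* **Full-model integration** uses `lsoda` at rtol $10^{-8}$ / atol
  $10^{-10}$. Negative excursions within the tolerance band
  ($> -10^{-8}$) are clamped to zero on output; anything larger aborts
  with a diagnostic rather than being silently repaired.
* **Equilibrium enumeration** solves, for every nonempty support
  $J \subseteq \{1..N\}$, the bordered linear system $(\Lambda z)_i = c$
  on $J$, $\sum_J z_i = 1$ (compiled, RcppArmadillo). Feasibility demands
  all support frequencies $> 10^{-9}$; a condition estimate beyond
  $10^{12}$ marks the support degenerate (data, not an error — true
  degeneracy has measure zero under normal sampling). The common growth
  value $c$ equals $Q(z^*)$. Enumeration is exhaustive over $2^N - 1$
  supports with a guard at $N \le 16$.
* **Stability** is judged on the Jacobian restricted to the simplex
  tangent space $\{v : \sum v = 0\}$, evaluated in an orthonormal tangent
  basis so the spurious normal direction never enters the spectrum; for
  off-support strains the retained spectrum carries the invasion rates
  $\Theta((\Lambda z^*)_i - Q)$. Since $\Theta$ only scales the spectrum,
  classification is computed at $\Theta = 1$ with an absolute eigenvalue
  tolerance of $10^{-8}$: dominant real part below $-10^{-8}$ is stable,
  within $\pm 10^{-8}$ is *marginal* and counted unstable — this cleanly
  separates the genuine zero modes of the skew-symmetric limit from
  numerically tiny negatives.
* **Attractor classification** integrates to $\tau \le 5000$ by default
  and uses: field norm $< 10^{-8}$ plus proximity ($10^{-6}$) to an
  enumerated stable equilibrium for `fixed_point`; log running-minimum
  slope $< -10^{-3}$ per $\tau$ with $R^2 > 0.9$ and recurrent
  near-monodominance ($\max_i z_i > 0.9$) for `heteroclinic_like`
  (underflow below $\sim 10^{-300}$ also qualifies, as effective
  absorption); recurring peaks with period CV $< 0.1$ and minima bounded
  away from zero for `limit_cycle`; otherwise `undetermined`. These
  thresholds are ours — the source analysis classified visually.
  Converging spirals are reported as `fixed_point`.

## The two $\mu$ limits

As $\mu \to 0$ (co-colonization dominates), $\lambda_{ij} \to
\alpha_{ji} - \alpha_{jj}$ depends only on the resident: columns of $A$
set whole invasion profiles, independent niches are common, and many
stable (often vertex) equilibria coexist — multistability. As
$\mu \to \infty$, $\Lambda/\mu \to A^\top - A$ is skew-symmetric: the
zero-sum replicator with neutrally stable interior points, cycles, and —
at large finite $\mu$ — attracting heteroclinic networks. Only odd
numbers of strains can coexist there, with
$P(n = k) = \binom{N}{k} 2^{1-N}$ for odd $k$.

One subtlety deserves record. The cited combinatorial law for $\mu = 0$
with zero diagonal — "a feasible equilibrium with probability exactly
$2^{-n}$" — is a statement about generalized Lotka–Volterra systems,
where the steady state $x \propto$ solution of $A^\top y = \mathbf 1$
must itself be positive. The replicator *normalizes* frequencies, so the
mirrored all-negative solution branch also lands on the simplex: by the
column sign-flip symmetry of the i.i.d. ensemble the replicator
full-support equilibrium is feasible with probability $2^{1-n}$ (sanity
check at $n = 2$: feasibility iff $\alpha_{12}, \alpha_{21}$ share a
sign, probability $\tfrac12$). `feasibility_probability_experiment()`
therefore reports both fractions — `fraction_positive_growth` (common
growth $c > 0$; law $2^{-n}$) and `fraction_feasible` (either branch; law
$2^{1-n}$) — and the tests assert each against its own law.

## Ensemble experiments and what they show

The Monte-Carlo modules reproduce the coexistence phenomenology along the
$\mu$ gradient with scaled-down ensemble sizes chosen as the package's
default study design: 10,000 pairs for the pairwise-outcome experiment,
2,000 systems of $N = 10$ for the diversity–stability and strain-overlap
experiments, 1,000 systems per $\mu$ for the regime scan — sizes at which
every targeted percentage carries a binomial standard error of at most
$\sim 1.6$ points. With the compiled enumeration core the full set runs
in about a minute.

* `pairwise_outcome_fractions()`: exclusion rises from 50% at $\mu = 0$
  to 92% at $\mu = 5$; the independent oracle is the bivariate-normal
  orthant formula through
  $\rho(\mu) = -2\mu(1+\mu)/((1+\mu)^2 + \mu^2 + 1)$.
* `diversity_stability_experiment()` ($\mu = 0.05$): stable states are
  $\approx 2\%$ of all feasible steady states; within a support size,
  stability magnitude rises with evenness while feasibility falls,
  producing a peaked *effective stability* $f(E)\,s(E)$ at intermediate
  Shannon entropy, and a characteristic rank-abundance profile there.
  Entropy is binned into 20 equal-width bins on $[0, \ln N]$ — fine
  enough to resolve the peaks, coarse enough to avoid empty-bin noise at
  2,000 systems.
* `soi_experiment()` ($\mu = 0$): generic steady-state pairs share
  $\approx 20\%$ of strains (Jaccard), stable pairs are nearly disjoint
  (measured mean $\approx 3.6\%$, driven by the rare systems whose stable
  supports do overlap).
* `regime_scan()` over $\mu \in [0.01, 100]$: $\approx 80\%$ multistable
  at the low end; at the high end the no-stable-state fraction plateaus
  around 70% (measured 67–73% across seeds at 1,000 systems — the
  printed "more than 70%" sits at the edge of this sampling band).
* `nonoverlap_multistability_probability()`: disjoint-support
  multistability peaks near $\mu \approx 0.1$ ($\approx 60\%$ of systems)
  and vanishes by $\mu = 10$.
* `coexistence_count_distribution()`: mean coexisting-strain number grows
  with $\mu$; in the skew limit the attractor support is identified as
  the unique *saturated* feasible equilibrium (no off-support strain has
  positive invasion rate), and its size distribution matches the odd-only
  law above.

The worked epidemiological anchor: pneumococcal serotypes with
$\approx 90\%$ mutual inhibition in co-colonization ($k \approx 0.1$) and
$R_0 \approx 2$ give $\mu = 1/((R_0-1)k) = 10$ — a regime where
multistability is essentially impossible and a single stable equilibrium
is about as likely as complex unstable coexistence.

```{r example, eval = FALSE}
A <- draw_normalized_matrix(10, seed = 1)
L <- invasion_fitness_matrix(A, mu = single_to_cocolonization_ratio(2, 0.1))
rec <- stability(enumerate_equilibria(L, keep_infeasible = FALSE))
classify_system(rec)
```

## What the synthetic ensembles do and do not emulate

The generators reproduce the study conditions exactly: i.i.d. standard
normal trait deviations (optionally zero-diagonal or antisymmetrized),
scalar mean-field parameters, fixed seeds with a named RNG
(Mersenne-Twister / inversion normals) recorded in all provenance
metadata. They do **not** emulate heavy-tailed or empirically structured
interaction networks, host heterogeneity, seasonality, mutation, or
immune memory — so passing tests certify the mathematics of the
mean-field model and its reduction, not the behaviour of any particular
pathogen community. In the $\mu \to \infty$ limit the qualitative laws
are distribution-free, but at small $\mu$ the normal assumption matters
and other trait distributions would shift the numerical fractions.

## Known limitations

* Enumeration cost grows as $2^N$; the guard at $N \le 16$ reflects both
  runtime and the accumulation of near-degenerate supports at larger
  pools.
* `classify_attractor()` is heuristic: trajectories shorter than ~10
  oscillation periods, or chaotic ones, return `undetermined` (chaos is
  never claimed); stable spirals are folded into `fixed_point`, with the
  oscillatory transient visible only in the trajectory itself.
* Basins of attraction, permanence certificates, and bifurcation
  continuation in $\mu$ are out of scope.
* The phase relation between the community traits $q$ and $Q$ in the
  oscillatory regime is exposed descriptively (`trait_lag_correlation()`)
  without asserting synchrony or asynchrony.
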