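// Exhaustive steady-state enumeration for the N-strain replicator system
// dz_i/dtau = Theta * z_i * ((Lambda z)_i - Q(z)),  Q(z) = z' Lambda z.
//
// For every nonempty support J of {1..N} the candidate equilibrium solves the
// bordered linear system  (Lambda z)_i = c for i in J,  sum_{i in J} z_i = 1,
// z = 0 off-support.  Stability is judged on the Jacobian restricted to the
// simplex tangent space {v : sum v = 0}; Theta only scales the spectrum so the
// classification is computed at Theta = 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Orthonormal basis of {v : sum(v) = 0} (N x (N-1)).
static arma::mat tangent_basis(const arma::uword N) {
  arma::mat ones(1, N, arma::fill::ones);
  return arma::null(ones);
}

// Full N x N Jacobian of the replicator vector field at z (Theta = 1).
static arma::mat replicator_jacobian_arma(const arma::vec& z,
                                          const arma::mat& L) {
  const arma::uword N = z.n_elem;
  arma::vec w = L * z;
  double Q = arma::dot(z, w);
  arma::vec u = (L + L.t()) * z;
  arma::mat J(N, N);
  for (arma::uword i = 0; i < N; ++i) {
    for (arma::uword l = 0; l < N; ++l) {
      J(i, l) = z(i) * (L(i, l) - u(l));
      if (i == l) J(i, l) += w(i) - Q;
    }
  }
  return J;
}

// [[Rcpp::export]]
List enum_equilibria_cpp(const arma::mat& Lambda,
                         const double tol_feas,
                         const double cond_tol,
                         const double tol_eig,
                         const bool keep_infeasible,
                         const bool want_z) {
  const arma::uword N = Lambda.n_rows;
  if (Lambda.n_cols != N) stop("Lambda must be square");
  if (N < 1 || N > 16) stop("support enumeration limited to 1 <= N <= 16");

  const unsigned int n_masks = (1u << N) - 1u;
  const arma::mat E = tangent_basis(N);

  std::vector<int> mask_v, n_v;
  std::vector<int> feas_v, degen_v, stable_v, marg_v;
  std::vector<double> c_v, dom_v, ent_v, maxinv_v;
  std::vector<double> z_rows;

  mask_v.reserve(512);

  arma::uvec idx(N);
  for (unsigned int mask = 1; mask <= n_masks; ++mask) {
    arma::uword k = 0;
    for (arma::uword b = 0; b < N; ++b)
      if (mask & (1u << b)) idx(k++) = b;
    const arma::uvec sup = idx.head(k);

    arma::vec z(N, arma::fill::zeros);
    double c = 0.0;
    bool degenerate = false;
    bool feasible = true;

    if (k == 1) {
      z(sup(0)) = 1.0;
      c = Lambda(sup(0), sup(0));  // zero on a zero-diagonal Lambda
    } else {
      arma::mat M(k + 1, k + 1, arma::fill::zeros);
      M.submat(0, 0, k - 1, k - 1) = Lambda.submat(sup, sup);
      for (arma::uword j = 0; j < k; ++j) {
        M(j, k) = -1.0;
        M(k, j) = 1.0;
      }
      arma::vec b(k + 1, arma::fill::zeros);
      b(k) = 1.0;
      arma::vec x;
      const bool ok = arma::solve(x, M, b,
                                  arma::solve_opts::no_approx +
                                  arma::solve_opts::fast);
      if (!ok || !x.is_finite() || arma::rcond(M) < 1.0 / cond_tol) {
        degenerate = true;
        feasible = false;
      } else {
        for (arma::uword j = 0; j < k; ++j) z(sup(j)) = x(j);
        c = x(k);
        feasible = arma::all(x.head(k) > tol_feas);
      }
    }

    double dom = NA_REAL, entropy = NA_REAL;
    double max_inv = R_NegInf;
    bool stable = false, marginal = false;

    if (feasible) {
      entropy = 0.0;
      for (arma::uword j = 0; j < k; ++j) {
        const double zi = z(sup(j));
        entropy -= zi * std::log(zi);
      }
      const arma::vec w = Lambda * z;
      for (arma::uword b = 0; b < N; ++b) {
        if (!(mask & (1u << b))) {
          const double inv = w(b) - c;  // invasion rate of strain b (Theta = 1)
          if (inv > max_inv) max_inv = inv;
        }
      }
      if (N == 1) {
        dom = R_NegInf;
        stable = true;
      } else {
        const arma::mat J = replicator_jacobian_arma(z, Lambda);
        const arma::mat R = E.t() * J * E;
        arma::cx_vec ev;
        if (!arma::eig_gen(ev, R)) {
          degenerate = true;
          feasible = false;
        } else {
          dom = ev.n_elem ? arma::real(ev).max() : R_NegInf;
          marginal = std::abs(dom) <= tol_eig;
          stable = (dom < -tol_eig);
        }
      }
    }

    if (feasible || keep_infeasible) {
      mask_v.push_back((int)mask);
      n_v.push_back((int)k);
      feas_v.push_back(feasible ? 1 : 0);
      degen_v.push_back(degenerate ? 1 : 0);
      c_v.push_back(degenerate ? NA_REAL : c);
      dom_v.push_back(dom);
      ent_v.push_back(entropy);
      maxinv_v.push_back(feasible ? max_inv : NA_REAL);
      stable_v.push_back(stable ? 1 : 0);
      marg_v.push_back(marginal ? 1 : 0);
      if (want_z)
        for (arma::uword b = 0; b < N; ++b)
          z_rows.push_back(degenerate ? NA_REAL : z(b));
    }
  }

  const R_xlen_t nr = (R_xlen_t)mask_v.size();
  List out = List::create(
      _["support"] = IntegerVector(mask_v.begin(), mask_v.end()),
      _["n"] = IntegerVector(n_v.begin(), n_v.end()),
      _["feasible"] = LogicalVector(feas_v.begin(), feas_v.end()),
      _["degenerate"] = LogicalVector(degen_v.begin(), degen_v.end()),
      _["growth"] = NumericVector(c_v.begin(), c_v.end()),
      _["dominant_real"] = NumericVector(dom_v.begin(), dom_v.end()),
      _["marginal"] = LogicalVector(marg_v.begin(), marg_v.end()),
      _["stable"] = LogicalVector(stable_v.begin(), stable_v.end()),
      _["entropy"] = NumericVector(ent_v.begin(), ent_v.end()),
      _["max_invasion"] = NumericVector(maxinv_v.begin(), maxinv_v.end()));
  if (want_z) {
    NumericMatrix zm(N, nr);  // filled column-wise, transpose in R
    std::copy(z_rows.begin(), z_rows.end(), zm.begin());
    out["z"] = zm;
  }
  return out;
}
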