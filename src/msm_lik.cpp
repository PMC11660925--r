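// Likelihood core for the continuous-time multi-state Markov model with
// panel-observed states and piecewise-constant covariates. Transition
// probability matrices over observation intervals are matrix exponentials
// of generator matrices, computed once per unique (covariate row, interval
// length) combination and shared across the intervals that use it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& A) {
  return arma::expmat(A);
}

// exp(Q * dt) for a generator matrix (zero row sums, non-negative
// off-diagonals) by uniformization: with lambda >= max_r |Q_rr| the matrix
// M = I + Q/lambda is stochastic and exp(Q dt) = sum_k Pois(k; lambda dt)
// M^k, a series of non-negative terms with an exact Poisson tail bound --
// no cancellation, accurate to the 1e-12 level. Returns false (caller
// falls back to the general Pade routine) when the rate mass is too large
// for the series.
static bool expm_generator(const arma::mat& Q, double dt, arma::mat& P,
                           arma::mat& M, arma::mat& T, arma::mat& W) {
  int n = Q.n_rows;
  double lam = 0.0;
  for (int r = 0; r < n; ++r) lam = std::max(lam, -Q(r, r));
  if (!std::isfinite(lam)) return false;
  double a = lam * dt;
  if (a > 500.0) return false;       // extreme proposal: use Pade instead
  P.eye(n, n);
  if (a <= 0.0) return true;
  M = arma::eye(n, n) + Q * (dt / a);
  T.eye(n, n);
  double w = std::exp(-a);
  double wsum = w;
  P *= w;
  int kmax = (int)(a + 12.0 * std::sqrt(a + 1.0) + 60.0);
  for (int k = 1; k <= kmax; ++k) {
    W = T * M;
    T.swap(W);
    w *= a / k;
    P += w * T;
    wsum += w;
    if (1.0 - wsum < 1e-15) break;
  }
  return P.is_finite();
}

// Per-interval log-likelihood contributions.
//
// theta     parameter vector (baseline log intensities then coefficients)
// Zu        unique covariate rows (n_comb x n_cov)
// dtu       interval length (years) per unique combination
// comb      0-based index into the unique combinations, per interval
// from, to  0-based observed states at the interval's endpoints
// is_death  1 if the interval ends in an exactly observed death
// tr_*      transition map (0-based states / parameter indices)
// death_state 0-based index of the absorbing death state
// [[Rcpp::export]]
NumericVector cpp_panel_loglik(const arma::vec& theta, const arma::mat& Zu,
                               const arma::vec& dtu,
                               const IntegerVector& comb,
                               const IntegerVector& from,
                               const IntegerVector& to,
                               const IntegerVector& is_death,
                               const IntegerVector& tr_from,
                               const IntegerVector& tr_to,
                               const IntegerVector& q0_idx,
                               const List& beta_idx, const List& z_cols,
                               int n_states, int death_state) {
  int n_comb = Zu.n_rows;
  int K = tr_from.size();

  // flatten the per-transition index lists once
  std::vector<std::vector<int> > bidx(K), zidx(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector bi = beta_idx[k];
    IntegerVector zc = z_cols[k];
    bidx[k].assign(bi.begin(), bi.end());
    zidx[k].assign(zc.begin(), zc.end());
  }

  bool any_death = false;
  for (int i = 0; i < is_death.size(); ++i) {
    if (is_death[i]) { any_death = true; break; }
  }

  arma::cube Pcube(n_states, n_states, n_comb);
  arma::cube Qcube;
  if (any_death) Qcube.set_size(n_states, n_states, n_comb);
  std::vector<char> ok(n_comb, 1);

  arma::mat Q(n_states, n_states), P(n_states, n_states),
    M(n_states, n_states), T(n_states, n_states), W(n_states, n_states);
  for (int c = 0; c < n_comb; ++c) {
    Q.zeros();
    const double* zrow = Zu.memptr();  // column-major: Zu(c, j)
    for (int k = 0; k < K; ++k) {
      double lp = theta[q0_idx[k]];
      const std::vector<int>& bi = bidx[k];
      const std::vector<int>& zc = zidx[k];
      for (size_t j = 0; j < bi.size(); ++j) {
        lp += theta[bi[j]] * zrow[(size_t)zc[j] * n_comb + c];
      }
      Q(tr_from[k], tr_to[k]) += std::exp(lp);
    }
    for (int r = 0; r < n_states; ++r) {
      double rowsum = 0.0;
      for (int s = 0; s < n_states; ++s) if (s != r) rowsum += Q(r, s);
      Q(r, r) = -rowsum;
    }
    if (!Q.is_finite()) { ok[c] = 0; continue; }
    bool done = expm_generator(Q, dtu[c], P, M, T, W);
    if (!done) {
      // extreme parameter proposals during optimisation: fall back, and on
      // failure flag the combination so the likelihood becomes -Inf and
      // the optimiser backtracks rather than erroring
      try {
        P = arma::expmat(Q * dtu[c]);
        done = P.is_finite();
      } catch (...) {
        done = false;
      }
    }
    if (!done) { ok[c] = 0; continue; }
    Pcube.slice(c) = P;
    if (any_death) Qcube.slice(c) = Q;
  }

  int n = comb.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = comb[i];
    if (!ok[c]) { out[i] = R_NegInf; continue; }
    double p;
    if (is_death[i]) {
      // density of an exactly observed death at the interval end: sum over
      // the transient state occupied just before death
      p = 0.0;
      for (int s = 0; s < n_states; ++s) {
        if (s == death_state) continue;
        p += Pcube(from[i], s, c) * Qcube(s, death_state, c);
      }
    } else {
      p = Pcube(from[i], to[i], c);
    }
    out[i] = (p > 0.0) ? std::log(p) : R_NegInf;
  }
  return out;
}
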