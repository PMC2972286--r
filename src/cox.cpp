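// Newton-Raphson maximization of the Cox partial likelihood with Breslow
// tie handling. Written as a batch scanner: the gene-set permutation test
// refits one small Cox model per gene per permutation, so per-fit overhead
// has to be microseconds, not milliseconds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Breslow partial log-likelihood, gradient and (negative) Hessian at beta.
// ord holds 0-based indices sorted by time in DECREASING order (ties adjacent)
// so risk-set sums accumulate in one pass.
static double breslow_ll(const arma::vec& time, const arma::ivec& status,
                         const arma::mat& X, const arma::uvec& ord,
                         const arma::vec& beta,
                         arma::vec* grad, arma::mat* hess) {
  const arma::uword n = time.n_elem;
  const arma::uword p = X.n_cols;
  arma::vec eta = (p > 0) ? arma::vec(X * beta) : arma::vec(n, arma::fill::zeros);
  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  if (grad) grad->zeros(p);
  if (hess) hess->zeros(p, p);
  double ll = 0.0;
  arma::uword i = 0;
  while (i < n) {
    const double t = time(ord(i));
    arma::uword j = i;
    while (j < n && time(ord(j)) == t) {
      const arma::uword idx = ord(j);
      const double r = std::exp(eta(idx));
      S0 += r;
      if (p > 0) {
        const arma::rowvec xi = X.row(idx);
        S1 += r * xi.t();
        if (hess) S2 += r * (xi.t() * xi);
      }
      ++j;
    }
    int d = 0;
    for (arma::uword k = i; k < j; ++k) {
      const arma::uword idx = ord(k);
      if (status(idx) == 1) {
        ++d;
        ll += eta(idx);
        if (grad && p > 0) *grad += X.row(idx).t();
      }
    }
    if (d > 0) {
      ll -= d * std::log(S0);
      if (grad && p > 0) *grad -= d * (S1 / S0);
      if (hess && p > 0) *hess += d * (S2 / S0 - (S1 * S1.t()) / (S0 * S0));
    }
    i = j;
  }
  return ll;
}

struct NewtonResult {
  arma::vec beta;
  arma::vec se;
  double loglik;
  bool converged;
  int iter;
};

// Step-halving Newton. Monotone-likelihood (separation) is caught by capping
// |beta|; singular information (collinearity) by a failed solve.
static NewtonResult newton_fit(const arma::vec& time, const arma::ivec& status,
                               const arma::mat& X, const arma::uvec& ord,
                               arma::vec beta, int max_iter, double tol,
                               double beta_cap) {
  const arma::uword p = X.n_cols;
  NewtonResult res;
  res.converged = false;
  res.iter = 0;
  arma::vec grad(p);
  arma::mat hess(p, p);
  double ll = breslow_ll(time, status, X, ord, beta, &grad, &hess);
  bool capped = false, singular = false;
  for (int it = 0; it < max_iter; ++it) {
    res.iter = it + 1;
    arma::vec step;
    const bool ok = arma::solve(step, hess, grad,
                                arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok || !step.is_finite()) { singular = true; break; }
    double fac = 1.0;
    arma::vec beta_new;
    double ll_new = -arma::datum::inf;
    for (int h = 0; h < 20; ++h) {
      beta_new = beta + fac * step;
      ll_new = breslow_ll(time, status, X, ord, beta_new, nullptr, nullptr);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      fac *= 0.5;
    }
    if (!std::isfinite(ll_new)) { singular = true; break; }
    beta = beta_new;
    if (arma::abs(beta).max() > beta_cap) {
      beta = arma::clamp(beta, -beta_cap, beta_cap);
      ll = breslow_ll(time, status, X, ord, beta, &grad, &hess);
      capped = true;
      break;
    }
    const double delta = ll_new - ll;
    ll = breslow_ll(time, status, X, ord, beta, &grad, &hess);
    if (std::abs(delta) < tol * (std::abs(ll) + 0.1)) {
      res.converged = true;
      break;
    }
  }
  if (singular) {
    res.beta = arma::vec(p, arma::fill::zeros);
    res.se = arma::vec(p); res.se.fill(arma::datum::nan);
    res.loglik = breslow_ll(time, status, X, ord, res.beta, nullptr, nullptr);
    res.converged = false;
    return res;
  }
  if (capped) res.converged = false;
  res.beta = beta;
  res.loglik = ll;
  arma::mat cov;
  if (p > 0 && arma::inv_sympd(cov, hess)) {
    res.se = arma::sqrt(cov.diag());
  } else if (p > 0 && arma::inv(cov, hess)) {
    res.se = arma::sqrt(arma::abs(cov.diag()));
  } else {
    res.se = arma::vec(p); res.se.fill(arma::datum::nan);
    res.converged = false;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_cox_fit(const arma::vec& time, const arma::ivec& status,
                 const arma::mat& X, const arma::uvec& ord,
                 const arma::vec& beta_init, int max_iter, double tol,
                 double beta_cap) {
  NewtonResult r = newton_fit(time, status, X, ord, beta_init, max_iter, tol, beta_cap);
  const double ll0 = breslow_ll(time, status, X, ord,
                                arma::vec(X.n_cols, arma::fill::zeros),
                                nullptr, nullptr);
  return List::create(_["coef"] = r.beta, _["se"] = r.se,
                      _["loglik"] = r.loglik, _["loglik_null"] = ll0,
                      _["converged"] = r.converged, _["iter"] = r.iter);
}

// [[Rcpp::export]]
double cpp_cox_loglik(const arma::vec& time, const arma::ivec& status,
                      const arma::mat& X, const arma::uvec& ord,
                      const arma::vec& beta) {
  return breslow_ll(time, status, X, ord, beta, nullptr, nullptr);
}

// Per-gene scan: for each column g of G fit Cox on [g, Z], returning the gene
// coefficient, its se, Wald z and the fitted log-likelihood. Z may have zero
// columns. Genes with singular information, capped coefficients or
// non-convergence are flagged (conv = 0).
// [[Rcpp::export]]
NumericMatrix cpp_cox_scan(const arma::vec& time, const arma::ivec& status,
                           const arma::mat& G, const arma::mat& Z,
                           const arma::uvec& ord, const arma::vec& z_init,
                           int max_iter, double tol, double beta_cap) {
  const arma::uword n = time.n_elem;
  const arma::uword q = Z.n_cols;
  const arma::uword ng = G.n_cols;
  NumericMatrix out(ng, 5);  // coef, se, z, loglik, conv
  arma::mat X(n, q + 1);
  if (q > 0) X.cols(1, q) = Z;
  arma::vec init(q + 1, arma::fill::zeros);
  if (q > 0) init.subvec(1, q) = z_init;
  for (arma::uword g = 0; g < ng; ++g) {
    X.col(0) = G.col(g);
    // degenerate gene column: no information
    if (arma::var(X.col(0)) < 1e-14) {
      out(g, 0) = 0.0; out(g, 1) = NA_REAL; out(g, 2) = 0.0;
      out(g, 3) = NA_REAL; out(g, 4) = 0.0;
      continue;
    }
    NewtonResult r = newton_fit(time, status, X, ord, init, max_iter, tol, beta_cap);
    const bool ok = r.converged && std::isfinite(r.se(0)) && r.se(0) > 0;
    out(g, 0) = r.beta(0);
    out(g, 1) = r.se(0);
    out(g, 2) = ok ? r.beta(0) / r.se(0) : 0.0;
    out(g, 3) = r.loglik;
    out(g, 4) = ok ? 1.0 : 0.0;
  }
  return out;
}

// Randomization-step moments: mean and SD of the maxmean statistic over R
// gene sets of each requested size drawn without replacement (partial
// Fisher-Yates) from the scored universe. Uses R's RNG, so results are
// deterministic under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_maxmean_moments(const arma::vec& z, const arma::ivec& sizes,
                                  int R) {
  const int m = z.n_elem;
  std::vector<int> idx(m);
  std::iota(idx.begin(), idx.end(), 0);
  NumericMatrix out(sizes.n_elem, 2);
  for (int si = 0; si < (int)sizes.n_elem; ++si) {
    const int s = sizes(si);
    double sum = 0.0, sumsq = 0.0;
    for (int r = 0; r < R; ++r) {
      for (int k = 0; k < s; ++k) {
        int j = k + (int)(unif_rand() * (m - k));
        if (j >= m) j = m - 1;
        std::swap(idx[k], idx[j]);
      }
      double sp = 0.0, sn = 0.0;
      for (int k = 0; k < s; ++k) {
        const double v = z(idx[k]);
        if (v > 0) sp += v; else sn -= v;
      }
      sp /= s; sn /= s;
      const double mm = (sp >= sn) ? sp : -sn;
      sum += mm; sumsq += mm * mm;
    }
    const double mu = sum / R;
    const double var = (sumsq - R * mu * mu) / (R - 1);
    out(si, 0) = mu;
    out(si, 1) = var > 0 ? std::sqrt(var) : 0.0;
  }
  return out;
}
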