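// Marginal-likelihood engine for the fractional-polynomial linear mixed
// model: per-child V_i = Z_i G Z_i' + sigma2 * C_i(rho), fixed effects
// profiled out by generalized least squares, optional REML adjustment and
// BLUP back-solve. Children are independent, so everything accumulates
// over per-child Cholesky factorizations.
#define ARMA_WARN_LEVEL 0  // failures are detected via return codes
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// cov_code: 0 = variance_components (independent residuals)
//           1 = compound_symmetry
//           2 = autoregressive_spatial_power  rho^|t_j - t_k|
//           3 = autoregressive_by_order       rho^|j - k|
static mat resid_cor(const vec& t, double rho, int cov_code) {
  const uword n = t.n_elem;
  mat C(n, n, fill::eye);
  if (cov_code == 1) {
    for (uword i = 0; i < n; ++i)
      for (uword j = 0; j < i; ++j) { C(i, j) = rho; C(j, i) = rho; }
  } else if (cov_code == 2) {
    for (uword i = 0; i < n; ++i)
      for (uword j = 0; j < i; ++j) {
        double v = std::pow(rho, std::fabs(t[i] - t[j]));
        C(i, j) = v; C(j, i) = v;
      }
  } else if (cov_code == 3) {
    for (uword i = 0; i < n; ++i)
      for (uword j = 0; j < i; ++j) {
        double v = std::pow(rho, double(i - j));
        C(i, j) = v; C(j, i) = v;
      }
  }
  return C;
}

// [[Rcpp::export]]
Rcpp::List lmm_eval_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::vec& ages,
                        const arma::ivec& starts, const arma::ivec& lens,
                        const arma::uvec& re_cols, const arma::vec& re_var,
                        double sigma2, double rho, int cov_code,
                        bool reml, bool want_effects) {
  const uword p = X.n_cols, nch = starts.n_elem;
  const double n_tot = double(y.n_elem);
  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  double yVy = 0.0, logdet = 0.0;
  mat G = diagmat(re_var);

  for (uword i = 0; i < nch; ++i) {
    uword s = uword(starts[i]), n = uword(lens[i]);
    mat Xi = X.rows(s, s + n - 1);
    mat Zi = Xi.cols(re_cols);
    vec yi = y.subvec(s, s + n - 1);
    vec ti = ages.subvec(s, s + n - 1);
    mat V = symmatu(Zi * G * Zi.t() + sigma2 * resid_cor(ti, rho, cov_code));
    mat L;
    if (!chol(L, V, "lower"))
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("child") = int(i) + 1);
    mat W = join_rows(yi, Xi);
    mat U = solve(trimatl(L), W);           // L^{-1} [y X]
    vec uy = U.col(0);
    mat UX = U.cols(1, p);
    A += UX.t() * UX;
    b += UX.t() * uy;
    yVy += dot(uy, uy);
    logdet += 2.0 * accu(log(L.diag()));
  }

  vec beta;
  if (!solve(beta, A, b, solve_opts::likely_sympd + solve_opts::no_approx))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("child") = -1);
  double quad = yVy - 2.0 * dot(b, beta) + as_scalar(beta.t() * A * beta);
  double m2ll = logdet + quad + n_tot * std::log(2.0 * M_PI);
  if (reml) {
    double ldA, sign;
    log_det(ldA, sign, A);
    m2ll += ldA - double(p) * std::log(2.0 * M_PI);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("m2ll") = m2ll,
    Rcpp::Named("beta") = beta);
  if (want_effects) {
    mat Ainv = inv_sympd(A);
    mat blup(nch, re_cols.n_elem, fill::zeros);
    for (uword i = 0; i < nch; ++i) {
      uword s = uword(starts[i]), n = uword(lens[i]);
      mat Xi = X.rows(s, s + n - 1);
      mat Zi = Xi.cols(re_cols);
      vec yi = y.subvec(s, s + n - 1);
      vec ti = ages.subvec(s, s + n - 1);
      mat V = symmatu(Zi * G * Zi.t() + sigma2 * resid_cor(ti, rho, cov_code));
      mat L = chol(V, "lower");
      vec r = yi - Xi * beta;
      vec Vr = solve(trimatu(L.t()), solve(trimatl(L), r));
      blup.row(i) = (G * Zi.t() * Vr).t();
    }
    out["beta_cov"] = Ainv;
    out["blup"] = blup;
  }
  return out;
}

// Plain marginal -2 log-likelihood at GIVEN fixed effects (no profiling);
// used by the standalone likelihood evaluator.
// [[Rcpp::export]]
double lmm_m2ll_fixed_cpp(const arma::vec& y, const arma::mat& X,
                          const arma::vec& ages,
                          const arma::ivec& starts, const arma::ivec& lens,
                          const arma::uvec& re_cols, const arma::vec& re_var,
                          double sigma2, double rho, int cov_code,
                          const arma::vec& beta) {
  const uword nch = starts.n_elem;
  double m2ll = double(y.n_elem) * std::log(2.0 * M_PI);
  mat G = diagmat(re_var);
  for (uword i = 0; i < nch; ++i) {
    uword s = uword(starts[i]), n = uword(lens[i]);
    mat Xi = X.rows(s, s + n - 1);
    mat Zi = Xi.cols(re_cols);
    vec ri = y.subvec(s, s + n - 1) - Xi * beta;
    vec ti = ages.subvec(s, s + n - 1);
    mat V = symmatu(Zi * G * Zi.t() + sigma2 * resid_cor(ti, rho, cov_code));
    mat L;
    if (!chol(L, V, "lower"))
      Rcpp::stop("residual covariance not positive definite for child %d",
                 int(i) + 1);
    vec u = solve(trimatl(L), ri);
    m2ll += 2.0 * accu(log(L.diag())) + dot(u, u);
  }
  return m2ll;
}
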