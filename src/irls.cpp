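#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted logistic regression by iteratively reweighted least squares.
// Maximizes the weight-multiplied log-likelihood (weights act as frequency
// multipliers); convergence on relative deviance change < tol, with step
// halving if a Newton step increases the deviance.
// [[Rcpp::export(name = ".irls_logistic")]]
Rcpp::List irls_logistic(const arma::mat& X, const arma::vec& y,
                         const arma::vec& w, Rcpp::Nullable<Rcpp::NumericVector> start,
                         double tol = 1e-8, int maxit = 100) {
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  if (start.isNotNull()) {
    Rcpp::NumericVector s(start);
    if ((uword)s.size() == p) beta = vec(s.begin(), p);
  }

  auto deviance = [&](const vec& mu) {
    vec m = clamp(mu, 1e-12, 1.0 - 1e-12);
    return -2.0 * accu(w % (y % log(m) + (1.0 - y) % log(1.0 - m)));
  };

  vec eta = X * beta;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double dev = deviance(mu);
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    vec wv = w % mu % (1.0 - mu);
    // guard against zero working weights at extreme fitted values
    wv = clamp(wv, 1e-12, datum::inf);
    mat Xw = X.each_col() % wv;
    mat H = X.t() * Xw;
    vec score = X.t() * (w % (y - mu));
    vec step;
    bool ok = solve(step, H, score, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      ok = solve(step, H, score); // fall back to generic solver
      if (!ok) break;
    }
    double fac = 1.0;
    vec beta_new, mu_new;
    double dev_new = datum::inf;
    for (int half = 0; half < 30; ++half) {
      beta_new = beta + fac * step;
      mu_new = 1.0 / (1.0 + exp(-(X * beta_new)));
      dev_new = deviance(mu_new);
      if (std::isfinite(dev_new) && dev_new <= dev + 1e-10) break;
      fac *= 0.5;
    }
    double delta = std::abs(dev_new - dev) / (std::abs(dev_new) + 0.1);
    beta = beta_new;
    mu = mu_new;
    dev = dev_new;
    if (delta < tol) { converged = true; break; }
  }

  bool separation = any(mu < 1e-8) || any(mu > 1.0 - 1e-8) ||
    any(abs(beta) > 15.0);

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("separation") = separation,
    Rcpp::Named("fitted_min") = mu.min(),
    Rcpp::Named("fitted_max") = mu.max());
}
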