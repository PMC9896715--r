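// Negative-binomial GLM fitting for many genes sharing one design matrix.
// Log link, fixed per-gene dispersion alpha (var = mu + alpha*mu^2), size
// factors as offsets.  Fisher scoring / IRLS; the weight for the log link is
// w = mu / (1 + alpha*mu).  Reported estimate/SE are for a user-supplied
// contrast c'beta on the natural-log scale.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".nb_glm_genewise")]]
List nb_glm_genewise(const arma::mat& counts,   // genes x samples
                     const arma::mat& X,        // samples x p (full rank)
                     const arma::vec& offset,   // log size factors, length n
                     const arma::vec& alpha,    // per-gene dispersion
                     const arma::vec& contrast, // length p
                     double ridge = 0.0,        // penalty on non-intercept
                     int max_iter = 50,
                     double tol = 1e-8) {
  const arma::uword G = counts.n_rows, n = counts.n_cols, p = X.n_cols;
  arma::vec est(G, arma::fill::zeros), se(G, arma::fill::value(NA_REAL));
  arma::ivec conv(G, arma::fill::zeros);

  arma::mat pen(p, p, arma::fill::zeros);
  if (ridge > 0) {
    pen.eye(p, p);
    pen *= ridge;
    pen(0, 0) = 0.0;  // never penalize the intercept
  }

  for (arma::uword g = 0; g < G; ++g) {
    arma::vec y = counts.row(g).t();
    if (arma::accu(y) <= 0) { est(g) = 0.0; se(g) = NA_REAL; continue; }
    const double a = alpha(g);

    // init from a log-linear least squares fit
    arma::vec z0 = arma::log(y + 0.5) - offset;
    arma::vec beta;
    bool ok = arma::solve(beta, X.t() * X + pen, X.t() * z0);
    if (!ok) { est(g) = NA_REAL; continue; }

    arma::mat info(p, p);
    bool converged = false;
    for (int it = 0; it < max_iter; ++it) {
      arma::vec eta = X * beta + offset;
      eta = arma::clamp(eta, -30.0, 30.0);
      arma::vec mu = arma::exp(eta);
      arma::vec w = mu / (1.0 + a * mu);
      arma::vec z = (eta - offset) + (y - mu) / mu;
      arma::mat Xw = X.each_col() % w;
      info = X.t() * Xw + pen;
      arma::vec beta_new;
      ok = arma::solve(beta_new, info, Xw.t() * z, arma::solve_opts::likely_sympd);
      if (!ok) break;
      double delta = arma::abs(beta_new - beta).max();
      beta = beta_new;
      if (delta < tol * (1.0 + arma::abs(beta).max())) { converged = true; break; }
    }
    if (!ok) { est(g) = NA_REAL; continue; }

    // refresh information at the final beta
    arma::vec eta = arma::clamp(X * beta + offset, -30.0, 30.0);
    arma::vec mu = arma::exp(eta);
    arma::vec w = mu / (1.0 + a * mu);
    info = X.t() * (X.each_col() % w) + pen;
    arma::mat info_inv;
    if (!arma::inv_sympd(info_inv, info)) {
      if (!arma::pinv(info_inv, info)) { est(g) = NA_REAL; continue; }
    }
    est(g) = arma::dot(contrast, beta);
    double v = arma::as_scalar(contrast.t() * info_inv * contrast);
    se(g) = (v > 0) ? std::sqrt(v) : NA_REAL;
    conv(g) = converged ? 1 : 0;
  }
  return List::create(_["estimate"] = est, _["se"] = se,
                      _["converged"] = conv);
}
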