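// REML likelihood kernel for the multilevel meta-regression.
//
// The marginal covariance is Sigma = V + tau2_s Zs Zs' + tau2_g Zg Zg'
//   + tau2_e [ (1 - rho) I + rho Ze Ze' ]   (compound symmetry within
// experiment). Sigma is block-diagonal over connected components of the
// grouping structure; the R side passes one small dense block per
// component (sampling covariance V, design X, outcome y, and 0/1
// same-study / same-genus / same-experiment indicator matrices).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Evaluate the restricted log-likelihood pieces for given variance
// components. Returns the negative REML log-likelihood (including
// constants) and, when full = true, the GLS coefficients and their
// covariance.
// [[Rcpp::export]]
List reml_eval_cpp(List blocks, double tau2_s, double tau2_g, double tau2_e,
                   double rho, int p, bool full) {
  double ldet = 0.0, ytSiy = 0.0;
  int k = 0;
  arma::mat XtSiX(p, p, arma::fill::zeros);
  arma::mat XtX(p, p, arma::fill::zeros);
  arma::vec XtSiy(p, arma::fill::zeros);

  int nb = blocks.size();
  for (int b = 0; b < nb; ++b) {
    List blk = blocks[b];
    arma::mat V = blk["V"];
    arma::mat X = blk["X"];
    arma::vec y = blk["y"];
    arma::mat Ms = blk["Ms"];
    arma::mat Mg = blk["Mg"];
    arma::mat Me = blk["Me"];
    int m = V.n_rows;
    k += m;

    arma::mat Sigma = V;
    if (tau2_s > 0.0) Sigma += tau2_s * Ms;
    if (tau2_g > 0.0) Sigma += tau2_g * Mg;
    if (tau2_e > 0.0) {
      Sigma += tau2_e * rho * Me;
      Sigma.diag() += tau2_e * (1.0 - rho);
    }

    arma::mat R;
    bool ok = arma::chol(R, Sigma);  // Sigma = R' R
    if (!ok)
      return List::create(_["nll"] = 1e10, _["ok"] = false);

    ldet += 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Xw = arma::solve(arma::trimatl(R.t()), X);
    arma::vec yw = arma::solve(arma::trimatl(R.t()), y);
    XtSiX += Xw.t() * Xw;
    XtX += X.t() * X;
    XtSiy += Xw.t() * yw;
    ytSiy += arma::dot(yw, yw);
  }

  arma::vec beta;
  bool ok2 = arma::solve(beta, XtSiX, XtSiy, arma::solve_opts::no_approx);
  if (!ok2)
    return List::create(_["nll"] = 1e10, _["ok"] = false);

  double ldet_X, sign;
  arma::log_det(ldet_X, sign, XtSiX);
  if (sign <= 0.0)
    return List::create(_["nll"] = 1e10, _["ok"] = false);

  // Harville convention: + (1/2) ln|X'X| so values are comparable across
  // standard REML implementations (constant in the variance components)
  double ldet_XtX, sign2;
  arma::log_det(ldet_XtX, sign2, XtX);

  double rss = ytSiy - arma::dot(beta, XtSiy);  // r' Sigma^-1 r
  double nll = 0.5 * (ldet + ldet_X + rss - ldet_XtX) +
    0.5 * (double)(k - p) * std::log(2.0 * M_PI);

  if (!full)
    return List::create(_["nll"] = nll, _["ok"] = true);

  arma::mat covb = arma::inv_sympd(XtSiX);
  return List::create(_["nll"] = nll, _["ok"] = true,
                      _["beta"] = beta, _["cov_beta"] = covb,
                      _["k"] = k);
}
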