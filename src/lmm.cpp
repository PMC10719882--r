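// Per-SNP linear mixed model scan: REML estimation of the variance ratio
// lambda = sigma_g^2 / sigma_e^2 on the eigenbasis of the kinship matrix
// (decomposed once in R), then GLS effect estimates and Wald tests.
//
// Model per SNP: y = W a + x b + g + e, Var(y) = tau^-1 (lambda K + I).
// In the eigenbasis K = U D U', H = lambda D + I is diagonal, so each
// restricted-likelihood evaluation is O(n q^2) with q = ncol([W x]).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct RemlFit {
  double logl;
  bool ok;
  arma::vec beta;
  arma::mat XtHXinv;
  double ypy;     // residual quadratic form y'Py
};

// Restricted log-likelihood (constants dropped) at fixed lambda.
RemlFit reml_eval(double lambda, const arma::vec& d, const arma::mat& Xf,
                  const arma::vec& y) {
  const arma::uword n = d.n_elem, q = Xf.n_cols;
  RemlFit out; out.ok = false; out.logl = -std::numeric_limits<double>::infinity();
  arma::vec h = lambda * d + 1.0;
  if (h.min() <= 0) return out;
  arma::vec w = 1.0 / h;
  arma::mat Xw = Xf.each_col() % w;
  arma::mat XtHX = Xf.t() * Xw;
  XtHX = 0.5 * (XtHX + XtHX.t());
  arma::vec XtHy = Xw.t() * y;
  double ytHy = arma::dot(y % w, y);
  arma::mat R;
  if (!arma::chol(R, XtHX)) return out;
  arma::vec beta = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), XtHy));
  double ypy = ytHy - arma::dot(XtHy, beta);
  // an exact linear fit drives the residual quadratic to zero; clamp so the
  // Wald statistic saturates instead of going undefined
  if (!(ypy > 0) || ypy < 1e-280) ypy = 1e-280;
  double logdet_XtHX = 2.0 * arma::sum(arma::log(R.diag()));
  double df = static_cast<double>(n - q);
  out.logl = -0.5 * arma::sum(arma::log(h)) - 0.5 * logdet_XtHX
             - 0.5 * df * std::log(ypy);
  out.beta = beta;
  out.ypy = ypy;
  arma::mat Rinv = arma::inv(arma::trimatu(R));
  out.XtHXinv = Rinv * Rinv.t();
  out.ok = true;
  return out;
}

// Coarse log10 grid then golden-section refinement of the REML surface.
double reml_maximize(const arma::vec& d, const arma::mat& Xf, const arma::vec& y,
                     double l_min, double l_max, int n_grid) {
  double lg_lo = std::log10(l_min), lg_hi = std::log10(l_max);
  int best = 0;
  double best_ll = -std::numeric_limits<double>::infinity();
  std::vector<double> grid(n_grid);
  for (int i = 0; i < n_grid; ++i) {
    grid[i] = lg_lo + (lg_hi - lg_lo) * i / (n_grid - 1.0);
    double ll = reml_eval(std::pow(10.0, grid[i]), d, Xf, y).logl;
    if (ll > best_ll) { best_ll = ll; best = i; }
  }
  double a = grid[std::max(0, best - 1)];
  double b = grid[std::min(n_grid - 1, best + 1)];
  const double gr = 0.3819660112501051;  // 2 - golden ratio
  double x1 = a + gr * (b - a), x2 = b - gr * (b - a);
  double f1 = reml_eval(std::pow(10.0, x1), d, Xf, y).logl;
  double f2 = reml_eval(std::pow(10.0, x2), d, Xf, y).logl;
  for (int it = 0; it < 60 && (b - a) > 1e-6; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = b - gr * (b - a);
      f2 = reml_eval(std::pow(10.0, x2), d, Xf, y).logl;
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = a + gr * (b - a);
      f1 = reml_eval(std::pow(10.0, x1), d, Xf, y).logl;
    }
  }
  return std::pow(10.0, 0.5 * (a + b));
}

}  // namespace

// [[Rcpp::export]]
List lmm_scan_cpp(const arma::vec& d, const arma::mat& UtW, const arma::vec& Uty,
                  const arma::mat& UtX, double l_min, double l_max, int n_grid,
                  double fixed_lambda) {
  const arma::uword n = d.n_elem, p = UtX.n_cols, c = UtW.n_cols;
  const arma::uword q = c + 1;
  if (n <= q) stop("too few samples for the covariate set");
  NumericVector beta(p, NA_REAL), se(p, NA_REAL), pwald(p, NA_REAL),
      lam(p, NA_REAL);
  arma::mat Xf(n, q);
  Xf.cols(0, c - 1) = UtW;
  double df = static_cast<double>(n - q);
  for (arma::uword j = 0; j < p; ++j) {
    Xf.col(c) = UtX.col(j);
    double lambda = fixed_lambda >= 0
        ? fixed_lambda
        : reml_maximize(d, Xf, Uty, l_min, l_max, n_grid);
    RemlFit fit = reml_eval(lambda, d, Xf, Uty);
    if (!fit.ok) continue;
    double b = fit.beta(c);
    double s2 = fit.ypy / df * fit.XtHXinv(c, c);
    if (!(s2 > 0)) continue;
    double Fstat = b * b / s2;
    beta[j] = b;
    se[j] = std::sqrt(s2);
    lam[j] = lambda;
    pwald[j] = R::pf(Fstat, 1.0, df, 0, 0);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["p_wald"] = pwald,
                      _["lambda"] = lam);
}

// Null-model REML (no SNP term): lambda-hat, its restricted log-likelihood,
// and the curvature of the restricted likelihood in log(lambda) for a
// Wald-style interval on h2 = lambda / (1 + lambda).
// [[Rcpp::export]]
List lmm_null_cpp(const arma::vec& d, const arma::mat& UtW, const arma::vec& Uty,
                  double l_min, double l_max, int n_grid) {
  double lambda = reml_maximize(d, UtW, Uty, l_min, l_max, n_grid);
  RemlFit fit = reml_eval(lambda, d, UtW, Uty);
  if (!fit.ok) stop("restricted likelihood not finite at the REML optimum");
  // numerical second derivative in t = log(lambda)
  double eps = 1e-3;
  double f0 = fit.logl;
  double fp = reml_eval(lambda * std::exp(eps), d, UtW, Uty).logl;
  double fm = reml_eval(lambda * std::exp(-eps), d, UtW, Uty).logl;
  double curv = (fp - 2.0 * f0 + fm) / (eps * eps);
  return List::create(_["lambda"] = lambda, _["logl"] = f0,
                      _["curvature_loglambda"] = curv);
}
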