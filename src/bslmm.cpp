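// Bayesian sparse linear mixed model MCMC.
//
// Working model on the kinship eigenbasis (K = U D U', y and X already
// projected against fixed covariates and rotated by U'):
//   y = X_gamma beta + u + e,   beta_j ~ N(0, sigma_a^2 / tau),
//   u ~ N(0, (sigma_b^2 / tau) D),  e ~ N(0, tau^-1 I),  p(tau) ~ 1/tau.
// Hyperparameters (h, rho, log pi) carry uniform priors and map to the
// variance scales through the expected variance decomposition:
//   sigma_a^2 = h rho / ((1 - h) pi p s_a),  sigma_b^2 = h (1-rho) / ((1-h) s_b)
// with s_a the mean SNP dosage variance and s_b = tr(K)/n.
//
// The sampler integrates beta and tau out of the acceptance ratio
// (Metropolis-Hastings on gamma via add/delete/swap with geometric repeats,
// random walks with boundary reflection on h, rho, log pi) and draws
// tau, beta, u only when a state is recorded, to report per-iteration
// PVE / PGE realised from the sampled components.
//
// All randomness comes from R's RNG so set.seed() in R fixes the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double H_EPS = 1e-5;  // reflection bounds keep h, rho inside (0,1)

struct LikParts {
  double logl;      // integrated log-likelihood (constants dropped)
  double quad;      // y'Sigma^-1 y up to tau scaling: yHy - sa2 m'B^-1 m
  arma::mat Rchol;  // chol of B = I + sa2 A (upper), empty when s = 0
};

// Integrated likelihood from the cached quadratic pieces.
LikParts eval_lik(const arma::mat& A, const arma::vec& m, double yHy,
                  double sum_log_h, double sa2, double nprime,
                  bool constant_lik) {
  LikParts out;
  const arma::uword s = m.n_elem;
  double logdetB = 0.0, quad = yHy;
  if (s > 0) {
    arma::mat B = sa2 * A;
    B.diag() += 1.0;
    if (!arma::chol(out.Rchol, B)) {
      out.logl = -std::numeric_limits<double>::infinity();
      out.quad = yHy;
      return out;
    }
    logdetB = 2.0 * arma::sum(arma::log(out.Rchol.diag()));
    arma::vec z = arma::solve(arma::trimatl(out.Rchol.t()), m);
    quad = yHy - sa2 * arma::dot(z, z);
  }
  if (quad < 1e-300) quad = 1e-300;
  out.quad = quad;
  out.logl = constant_lik
                 ? 0.0
                 : -0.5 * sum_log_h - 0.5 * logdetB - 0.5 * nprime * std::log(quad);
  return out;
}

double log_prior_gamma(arma::uword s, arma::uword p, double pi) {
  double pi_c = std::min(pi, 1.0 - 1e-12);
  return s * std::log(pi_c) + (p - s) * std::log1p(-pi_c);
}

// reflect a random-walk proposal into [lo, hi]
double reflect(double x, double lo, double hi) {
  double span = hi - lo;
  if (span <= 0) return lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

void move_probs(arma::uword s, arma::uword p, arma::uword smax, double* padd,
                double* pdel, double* pswap) {
  if (s == 0) { *padd = 1.0; *pdel = 0.0; *pswap = 0.0; }
  else if (s >= smax || s >= p) { *padd = 0.0; *pdel = 0.8; *pswap = 0.2; }
  else { *padd = 0.4; *pdel = 0.4; *pswap = 0.2; }
  if (s >= p) *pswap = 0.0;  // nothing outside to swap in
}

}  // namespace

// [[Rcpp::export]]
List bslmm_mcmc_cpp(const arma::vec& d, const arma::vec& ytil,
                    const arma::mat& UtX, const arma::vec& u1, double s_a,
                    double s_b, double nprime, int burn_in, int steps,
                    int record_pace, double h_step, double rho_step,
                    double logpi_step, int smax_in, bool constant_lik,
                    double geom_p) {
  const arma::uword n = d.n_elem, p = UtX.n_cols;
  if (p < 2) stop("BSLMM needs at least 2 SNPs");
  const arma::uword smax = std::min<arma::uword>(p, smax_in);
  const double logpi_lo = std::log(1.0 / p), logpi_hi = 0.0;

  RNGScope scope;

  // ---- state ----
  double h = R::runif(H_EPS, 1.0 - H_EPS);
  double rho = R::runif(H_EPS, 1.0 - H_EPS);
  double logpi = R::runif(logpi_lo, logpi_hi);
  std::vector<arma::uword> gam;
  arma::mat Xg(n, 0), A(0, 0);
  arma::vec m;

  auto sigma_a2 = [&](double h_, double rho_, double logpi_) {
    return h_ * rho_ / ((1.0 - h_) * std::exp(logpi_) * p * s_a);
  };
  auto sigma_b2 = [&](double h_, double rho_) {
    return h_ * (1.0 - rho_) / ((1.0 - h_) * s_b);
  };

  double sb2 = sigma_b2(h, rho), sa2 = sigma_a2(h, rho, logpi);
  arma::vec w = 1.0 / (sb2 * d + 1.0);
  double sum_log_h = -arma::sum(arma::log(w));
  double yHy = arma::dot(ytil % w, ytil);
  LikParts lik = eval_lik(A, m, yHy, sum_log_h, sa2, nprime, constant_lik);
  double lp = lik.logl + log_prior_gamma(0, p, std::exp(logpi));

  const int total = burn_in + steps;
  const int n_rec = steps / record_pace;
  arma::mat hyp(n_rec, 6);  // h rho pi n_gamma pve pge
  arma::vec pip_count(p, arma::fill::zeros);
  std::vector<std::vector<double>> beta_store(p);
  arma::vec u_mean(n, arma::fill::zeros);
  int rec = 0;
  arma::uvec acc(4, arma::fill::zeros), tries(4, arma::fill::zeros);

  std::vector<bool> in_gam(p, false);

  for (int it = 1; it <= total; ++it) {
    double coin = R::unif_rand();
    if (coin < 0.4) {
      // ---- gamma moves (geometric number of repeats) ----
      int reps = 1 + static_cast<int>(R::rgeom(geom_p));
      if (reps > 4) reps = 4;
      for (int r = 0; r < reps; ++r) {
        arma::uword s = gam.size();
        double padd, pdel, pswap;
        move_probs(s, p, smax, &padd, &pdel, &pswap);
        double mv = R::unif_rand();
        tries(0)++;
        if (mv < padd) {
          // add a uniformly chosen excluded SNP
          arma::uword j;
          do { j = static_cast<arma::uword>(R::unif_rand() * p); } while (in_gam[j] || j >= p);
          arma::vec x = UtX.col(j), wx = w % x;
          arma::vec v = Xg.t() * wx;
          double ajj = arma::dot(x, wx), mj = arma::dot(wx, ytil);
          arma::mat A2(s + 1, s + 1);
          if (s > 0) {
            A2.submat(0, 0, s - 1, s - 1) = A;
            A2.submat(0, s, s - 1, s) = v;
            A2.submat(s, 0, s, s - 1) = v.t();
          }
          A2(s, s) = ajj;
          arma::vec m2(s + 1);
          if (s > 0) m2.head(s) = m;
          m2(s) = mj;
          LikParts lik2 = eval_lik(A2, m2, yHy, sum_log_h, sa2, nprime, constant_lik);
          double lp2 = lik2.logl + log_prior_gamma(s + 1, p, std::exp(logpi));
          double padd2, pdel2, psw2;
          move_probs(s + 1, p, smax, &padd2, &pdel2, &psw2);
          double lqr = std::log(pdel2) - std::log(static_cast<double>(s + 1))
                       - std::log(padd) + std::log(static_cast<double>(p - s));
          if (std::log(R::unif_rand()) < lp2 - lp + lqr) {
            Xg.insert_cols(s, x);
            A = A2; m = m2; gam.push_back(j); in_gam[j] = true;
            lik = lik2; lp = lp2; acc(0)++;
          }
        } else if (mv < padd + pdel) {
          arma::uword k = static_cast<arma::uword>(R::unif_rand() * s);
          if (k >= s) k = s - 1;
          arma::mat A2 = A; A2.shed_row(k); A2.shed_col(k);
          arma::vec m2 = m; m2.shed_row(k);
          LikParts lik2 = eval_lik(A2, m2, yHy, sum_log_h, sa2, nprime, constant_lik);
          double lp2 = lik2.logl + log_prior_gamma(s - 1, p, std::exp(logpi));
          double padd2, pdel2, psw2;
          move_probs(s - 1, p, smax, &padd2, &pdel2, &psw2);
          double lqr = std::log(padd2) - std::log(static_cast<double>(p - s + 1))
                       - std::log(pdel) + std::log(static_cast<double>(s));
          if (std::log(R::unif_rand()) < lp2 - lp + lqr) {
            in_gam[gam[k]] = false;
            gam.erase(gam.begin() + k);
            Xg.shed_col(k);
            A = A2; m = m2; lik = lik2; lp = lp2; acc(0)++;
          }
        } else if (pswap > 0 && s > 0 && s < p) {
          arma::uword k = static_cast<arma::uword>(R::unif_rand() * s);
          if (k >= s) k = s - 1;
          arma::uword j;
          do { j = static_cast<arma::uword>(R::unif_rand() * p); } while (in_gam[j] || j >= p);
          arma::mat Xg2 = Xg; Xg2.shed_col(k);
          arma::mat A2 = A; A2.shed_row(k); A2.shed_col(k);
          arma::vec m2 = m; m2.shed_row(k);
          arma::vec x = UtX.col(j), wx = w % x;
          arma::vec v = Xg2.t() * wx;
          double ajj = arma::dot(x, wx), mj = arma::dot(wx, ytil);
          arma::uword s2 = s - 1;
          arma::mat A3(s, s);
          if (s2 > 0) {
            A3.submat(0, 0, s2 - 1, s2 - 1) = A2;
            A3.submat(0, s2, s2 - 1, s2) = v;
            A3.submat(s2, 0, s2, s2 - 1) = v.t();
          }
          A3(s2, s2) = ajj;
          arma::vec m3(s);
          if (s2 > 0) m3.head(s2) = m2;
          m3(s2) = mj;
          LikParts lik2 = eval_lik(A3, m3, yHy, sum_log_h, sa2, nprime, constant_lik);
          double lp2 = lik2.logl + log_prior_gamma(s, p, std::exp(logpi));
          if (std::log(R::unif_rand()) < lp2 - lp) {
            in_gam[gam[k]] = false;
            gam.erase(gam.begin() + k);
            gam.push_back(j); in_gam[j] = true;
            Xg2.insert_cols(s2, x);
            Xg = Xg2; A = A3; m = m3; lik = lik2; lp = lp2; acc(0)++;
          }
        }
      }
    } else {
      // ---- hyperparameter random walks ----
      int which = coin < 0.6 ? 1 : (coin < 0.8 ? 2 : 3);
      double h2 = h, rho2 = rho, logpi2 = logpi;
      if (which == 1) h2 = reflect(h + R::runif(-h_step, h_step), H_EPS, 1.0 - H_EPS);
      else if (which == 2) rho2 = reflect(rho + R::runif(-rho_step, rho_step), H_EPS, 1.0 - H_EPS);
      else logpi2 = reflect(logpi + R::runif(-logpi_step, logpi_step), logpi_lo, logpi_hi);
      tries(which)++;

      double sb2_2 = sigma_b2(h2, rho2), sa2_2 = sigma_a2(h2, rho2, logpi2);
      arma::uword s = gam.size();
      if (which == 3) {
        // only sigma_a^2 and the gamma prior change
        LikParts lik2 = eval_lik(A, m, yHy, sum_log_h, sa2_2, nprime, constant_lik);
        double lp2 = lik2.logl + log_prior_gamma(s, p, std::exp(logpi2));
        if (std::log(R::unif_rand()) < lp2 - lp) {
          logpi = logpi2; sa2 = sa2_2; lik = lik2; lp = lp2; acc(3)++;
        }
      } else {
        arma::vec w2 = 1.0 / (sb2_2 * d + 1.0);
        double slh2 = -arma::sum(arma::log(w2));
        double yHy2 = arma::dot(ytil % w2, ytil);
        arma::mat A2(s, s);
        arma::vec m2(s);
        if (s > 0) {
          arma::mat Xw = Xg.each_col() % w2;
          A2 = Xw.t() * Xg;
          A2 = 0.5 * (A2 + A2.t());
          m2 = Xw.t() * ytil;
        }
        LikParts lik2 = eval_lik(A2, m2, yHy2, slh2, sa2_2, nprime, constant_lik);
        double lp2 = lik2.logl + log_prior_gamma(s, p, std::exp(logpi));
        if (std::log(R::unif_rand()) < lp2 - lp) {
          h = h2; rho = rho2; sb2 = sb2_2; sa2 = sa2_2;
          w = w2; sum_log_h = slh2; yHy = yHy2;
          A = A2; m = m2; lik = lik2; lp = lp2; acc(which)++;
        }
      }
    }

    // ---- record ----
    if (it > burn_in && (it - burn_in) % record_pace == 0 && rec < n_rec) {
      arma::uword s = gam.size();
      double pve = NA_REAL, pge = NA_REAL;
      if (!constant_lik) {
        double tau = R::rgamma(0.5 * nprime, 2.0 / lik.quad);
        arma::vec beta(s);
        if (s > 0) {
          arma::vec z = arma::solve(arma::trimatl(lik.Rchol.t()), m);
          arma::vec mu = sa2 * arma::solve(arma::trimatu(lik.Rchol), z);
          arma::vec eps(s);
          for (arma::uword k = 0; k < s; ++k) eps(k) = norm_rand();
          beta = mu + std::sqrt(sa2 / tau)
                          * arma::solve(arma::trimatu(lik.Rchol), eps);
        }
        arma::vec xb = s > 0 ? arma::vec(Xg * beta) : arma::vec(n, arma::fill::zeros);
        arma::vec r = ytil - xb;
        arma::vec u(n);
        for (arma::uword i = 0; i < n; ++i) {
          double ci = 1.0 - w(i);
          u(i) = ci * r(i) + std::sqrt(std::max(ci, 0.0) / tau) * norm_rand();
        }
        arma::vec g = xb + u;
        double mg = arma::dot(u1, g) / n;
        double vg = (arma::dot(g, g) - n * mg * mg) / (n - 1.0);
        double mx = arma::dot(u1, xb) / n;
        double vx = (arma::dot(xb, xb) - n * mx * mx) / (n - 1.0);
        if (vg < 0) vg = 0;
        pve = vg / (vg + 1.0 / tau);
        pge = vg > 0 ? std::min(1.0, std::max(0.0, vx / vg)) : 0.0;
        u_mean += u;
        for (arma::uword k = 0; k < s; ++k) {
          pip_count(gam[k]) += 1.0;
          beta_store[gam[k]].push_back(beta(k));
        }
      } else {
        for (arma::uword k = 0; k < s; ++k) pip_count(gam[k]) += 1.0;
      }
      hyp(rec, 0) = h;
      hyp(rec, 1) = rho;
      hyp(rec, 2) = std::exp(logpi);
      hyp(rec, 3) = static_cast<double>(s);
      hyp(rec, 4) = pve;
      hyp(rec, 5) = pge;
      ++rec;
    }
  }

  if (rec > 0) u_mean /= rec;
  // per-SNP polygenic attribution: alpha = X' K^+ u_bar / p on the eigenbasis
  arma::vec dinv_u(n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i)
    if (d(i) > 1e-8) dinv_u(i) = u_mean(i) / d(i);
  arma::vec alpha = UtX.t() * dinv_u / p;

  List beta_samples(p);
  for (arma::uword j = 0; j < p; ++j)
    beta_samples[j] = NumericVector(beta_store[j].begin(), beta_store[j].end());

  return List::create(
      _["hyp"] = hyp, _["pip"] = pip_count / std::max(rec, 1),
      _["beta_samples"] = beta_samples, _["alpha"] = alpha,
      _["accept"] = acc, _["tries"] = tries, _["n_recorded"] = rec);
}
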