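// Two-locus D' from unphased dosages via the EM haplotype-frequency
// estimate (the only ambiguous cell of the 3x3 genotype table is the
// double heterozygote), plus the sliding-window pruner built on it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Returns D' in [0,1], or NA if either locus is monomorphic among the
// jointly observed calls. Dosages are alt-allele counts; NA allowed.
double dprime_pair(const double* x, const double* y, int n) {
  double cnt[3][3] = {{0}};
  int N = 0;
  for (int i = 0; i < n; ++i) {
    if (ISNAN(x[i]) || ISNAN(y[i])) continue;
    int a = static_cast<int>(x[i] + 0.5), b = static_cast<int>(y[i] + 0.5);
    if (a < 0 || a > 2 || b < 0 || b > 2) return NA_REAL;
    cnt[a][b] += 1.0;
    ++N;
  }
  if (N == 0) return NA_REAL;
  double tot = 2.0 * N;
  double pA = 0, pB = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      pA += a * cnt[a][b];
      pB += b * cnt[a][b];
    }
  pA /= tot; pB /= tot;  // alt-allele frequencies
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return NA_REAL;

  // haplotype counts fully determined except for the double-het cell
  double dh = cnt[1][1];
  double base11 = 2 * cnt[2][2] + cnt[2][1] + cnt[1][2];
  double base10 = 2 * cnt[2][0] + cnt[2][1] + cnt[1][0];
  double base01 = 2 * cnt[0][2] + cnt[0][1] + cnt[1][2];
  double base00 = 2 * cnt[0][0] + cnt[0][1] + cnt[1][0];
  double f11 = pA * pB, f10 = pA * (1 - pB), f01 = (1 - pA) * pB,
         f00 = (1 - pA) * (1 - pB);
  for (int it = 0; it < 100; ++it) {
    double denom = f11 * f00 + f10 * f01;
    double pc = denom > 0 ? f11 * f00 / denom : 0.5;  // coupling probability
    double n11 = base11 + dh * pc;
    double n10 = base10 + dh * (1 - pc);
    double n01 = base01 + dh * (1 - pc);
    double n00 = base00 + dh * pc;
    double g11 = n11 / tot, g10 = n10 / tot, g01 = n01 / tot, g00 = n00 / tot;
    double delta = std::fabs(g11 - f11);
    f11 = g11; f10 = g10; f01 = g01; f00 = g00;
    if (delta < 1e-12) break;
  }
  double D = f11 - pA * pB;
  double Dmax = D >= 0 ? std::min(pA * (1 - pB), (1 - pA) * pB)
                       : std::min(pA * pB, (1 - pA) * (1 - pB));
  if (Dmax <= 0) return NA_REAL;
  double dp = std::fabs(D) / Dmax;
  return dp > 1.0 ? 1.0 : dp;
}

}  // namespace

// [[Rcpp::export]]
double dprime_cpp(const NumericVector& x, const NumericVector& y) {
  if (x.size() != y.size()) stop("dosage vectors differ in length");
  return dprime_pair(REAL(x), REAL(y), x.size());
}

// Greedy sliding-window pruning: within each window, for every kept pair
// with D' >= threshold drop the later (larger-position) SNP. Columns of X
// must already be sorted by (chrom, pos); `chrom` codes restrict pairs to
// the same chromosome. Returns 1-based indices of retained SNPs.
// [[Rcpp::export]]
IntegerVector prune_dprime_cpp(const NumericMatrix& X, const IntegerVector& chrom,
                               int window, int step, double threshold) {
  const int n = X.nrow(), p = X.ncol();
  const double* xp = REAL(X);
  std::vector<bool> keep(p, true);
  for (int w0 = 0; w0 < p - 1; w0 += step) {
    int w1 = std::min(w0 + window, p);
    for (int i = w0; i < w1; ++i) {
      if (!keep[i]) continue;
      for (int j = i + 1; j < w1; ++j) {
        if (!keep[j] || chrom[i] != chrom[j]) continue;
        double dp = dprime_pair(xp + static_cast<size_t>(i) * n,
                                xp + static_cast<size_t>(j) * n, n);
        if (!ISNAN(dp) && dp >= threshold) keep[j] = false;
      }
    }
    if (w1 == p) break;
  }
  std::vector<int> out;
  for (int j = 0; j < p; ++j)
    if (keep[j]) out.push_back(j + 1);
  return wrap(out);
}
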