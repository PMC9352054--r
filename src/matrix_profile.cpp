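#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Multidimensional matrix profile over C channels: for each window start i,
// the minimum over all admissible starts j of the mean across channels of
// the z-normalized Euclidean distance between the length-m subsequences at
// i and j. Trivial matches are excluded within ceil(m/2) of self, and any
// window marked bad (e.g. covering an invalid frame) neither receives nor
// provides matches. Diagonal traversal with a sliding dot-product
// recurrence keeps the cost at O(C * T^2) with O(C * T) memory.
//
// series: T x C matrix; var_floor: lower bound applied to window variances.
// [[Rcpp::export]]
List mp_multidim(NumericMatrix series, int m, LogicalVector bad_start,
                 double var_floor) {
  const int T = series.nrow(), C = series.ncol();
  const int n = T - m + 1;
  const int excl = (m + 1) / 2;  // |i - j| < excl is a trivial match
  if (n < 1) stop("series shorter than the window");

  // rolling means and stds per channel
  std::vector<std::vector<double>> mu(C, std::vector<double>(n));
  std::vector<std::vector<double>> sig(C, std::vector<double>(n));
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int t = 0; t < T; ++t) {
      double v = series(t, c);
      s += v; s2 += v * v;
      if (t >= m) { double u = series(t - m, c); s -= u; s2 -= u * u; }
      if (t >= m - 1) {
        int i = t - m + 1;
        double mean = s / m;
        double var = s2 / m - mean * mean;
        if (var < var_floor) var = var_floor;
        mu[c][i] = mean;
        sig[c][i] = std::sqrt(var);
      }
    }
  }

  NumericVector prof(n, R_PosInf);
  IntegerVector idx(n, NA_INTEGER);

  std::vector<double> qt(C);
  for (int k = excl; k < n; ++k) {     // diagonal offset: j = i + k
    // initial dot products for i = 0
    for (int c = 0; c < C; ++c) {
      double q = 0;
      for (int t = 0; t < m; ++t) q += series(t, c) * series(t + k, c);
      qt[c] = q;
    }
    for (int i = 0; i + k < n; ++i) {
      int j = i + k;
      if (i > 0) {
        for (int c = 0; c < C; ++c) {
          qt[c] += series(i + m - 1, c) * series(j + m - 1, c)
                 - series(i - 1, c) * series(j - 1, c);
        }
      }
      if (bad_start[i] || bad_start[j]) continue;
      double dsum = 0;
      for (int c = 0; c < C; ++c) {
        double corr = (qt[c] - m * mu[c][i] * mu[c][j]) /
                      ((double)m * sig[c][i] * sig[c][j]);
        double d2 = 2.0 * m * (1.0 - corr);
        if (d2 < 0) d2 = 0;
        dsum += std::sqrt(d2);
      }
      double d = dsum / C;
      if (d < prof[i]) { prof[i] = d; idx[i] = j + 1; }  // 1-based partner
      if (d < prof[j]) { prof[j] = d; idx[j] = i + 1; }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (bad_start[i]) { prof[i] = R_PosInf; idx[i] = NA_INTEGER; }
    else if (!R_finite(prof[i])) idx[i] = NA_INTEGER;
  }
  return List::create(_["profile"] = prof, _["index"] = idx);
}
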