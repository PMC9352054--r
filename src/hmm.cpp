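#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp_row(const std::vector<double>& v) {
  double mx = R_NegInf;
  for (double x : v) if (x > mx) mx = x;
  if (!R_finite(mx)) return R_NegInf;
  double s = 0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// Log-space forward-backward for one observation sequence.
// logdens: T x K per-frame per-state Gaussian log densities.
// Returns log-likelihood, posterior state probabilities gamma (T x K),
// expected transition counts xi_sum (K x K) and the posterior of the first
// frame (for initial-probability updates).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix alpha(T, K), beta(T, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) alpha(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = alpha(t - 1, j) + logA(j, k);
      alpha(t, k) = logsumexp_row(tmp) + logdens(t, k);
    }
  }
  std::vector<double> last(K);
  for (int k = 0; k < K; ++k) last[k] = alpha(T - 1, k);
  const double loglik = logsumexp_row(last);

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        tmp[j] = logA(k, j) + logdens(t + 1, j) + beta(t + 1, j);
      beta(t, k) = logsumexp_row(tmp);
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(alpha(t, k) + beta(t, k) - loglik);

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(alpha(t, j) + logA(j, k) + logdens(t + 1, k) +
                             beta(t + 1, k) - loglik);

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi);
}

// Exact Viterbi path (1-based state labels) for one sequence.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0; double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
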