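#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Exact t-SNE with sparse input similarities (perplexity-calibrated over a
// k-nearest-neighbor graph) and dense O(n^2) repulsive forces. Two
// optimization phases with distinct exaggeration factors implement the
// usual early-exaggeration schedule. Deterministic given Y0.
//
// nn_index: n x k 1-based neighbor indices (self excluded)
// nn_dist2: n x k squared distances to those neighbors
// Y0:       n x 2 initial embedding (e.g. scaled PCA)
// [[Rcpp::export]]
NumericMatrix tsne_embed(IntegerMatrix nn_index, NumericMatrix nn_dist2,
                         double perplexity, NumericMatrix Y0,
                         double exagg1, int iters1,
                         double exagg2, int iters2,
                         double learning_rate) {
  const int n = nn_index.nrow(), k = nn_index.ncol();
  const double logU = std::log(perplexity);

  // conditional probabilities p_{j|i} via binary search on precision beta
  std::vector<std::unordered_map<int, double>> P(n);
  std::vector<double> pj(k);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = R_NegInf, betamax = R_PosInf;
    double H = 0, psum = 0;
    for (int it = 0; it < 64; ++it) {
      psum = 0; H = 0;
      for (int j = 0; j < k; ++j) {
        pj[j] = std::exp(-beta * nn_dist2(i, j));
        psum += pj[j];
      }
      if (psum <= 0) psum = 1e-300;
      for (int j = 0; j < k; ++j) {
        double p = pj[j] / psum;
        if (p > 1e-300) H -= p * std::log(p);
      }
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {  // entropy too high -> sharpen
        betamin = beta;
        beta = R_finite(betamax) ? (beta + betamax) / 2 : beta * 2;
      } else {
        betamax = beta;
        beta = R_finite(betamin) ? (beta + betamin) / 2 : beta / 2;
      }
    }
    for (int j = 0; j < k; ++j) {
      double p = pj[j] / psum;
      if (p > 1e-12) P[i][nn_index(i, j) - 1] += p;
    }
  }

  // symmetrize: P_ij = (p_{j|i} + p_{i|j}) / (2n)
  std::vector<std::unordered_map<int, double>> Ps(n);
  for (int i = 0; i < n; ++i)
    for (auto& kv : P[i]) {
      Ps[i][kv.first] += kv.second / (2.0 * n);
      Ps[kv.first][i] += kv.second / (2.0 * n);
    }
  P.clear();

  NumericMatrix Y = clone(Y0);
  std::vector<double> uY(2 * n, 0.0), gains(2 * n, 1.0), grad(2 * n);
  std::vector<double> attr(2 * n), rep(2 * n);

  int total = iters1 + iters2;
  for (int iter = 0; iter < total; ++iter) {
    const double exagg = iter < iters1 ? exagg1 : exagg2;
    const double momentum = iter < iters1 ? 0.5 : 0.8;

    std::fill(attr.begin(), attr.end(), 0.0);
    std::fill(rep.begin(), rep.end(), 0.0);

    // attractive forces over the sparse P
    for (int i = 0; i < n; ++i)
      for (auto& kv : Ps[i]) {
        int j = kv.first;
        double dy0 = Y(i, 0) - Y(j, 0), dy1 = Y(i, 1) - Y(j, 1);
        double q = 1.0 / (1.0 + dy0 * dy0 + dy1 * dy1);
        double w = kv.second * q;
        attr[2 * i] += w * dy0;
        attr[2 * i + 1] += w * dy1;
      }

    // repulsive forces, dense
    double Z = 0;
    for (int i = 0; i < n; ++i) {
      double yi0 = Y(i, 0), yi1 = Y(i, 1);
      for (int j = i + 1; j < n; ++j) {
        double dy0 = yi0 - Y(j, 0), dy1 = yi1 - Y(j, 1);
        double q = 1.0 / (1.0 + dy0 * dy0 + dy1 * dy1);
        double q2 = q * q;
        Z += 2 * q;
        rep[2 * i] += q2 * dy0;     rep[2 * i + 1] += q2 * dy1;
        rep[2 * j] -= q2 * dy0;     rep[2 * j + 1] -= q2 * dy1;
      }
    }
    if (Z <= 0) Z = 1e-12;

    for (int i = 0; i < 2 * n; ++i) {
      grad[i] = 4.0 * (exagg * attr[i] - rep[i] / Z);
      gains[i] = ((grad[i] > 0) != (uY[i] > 0)) ? gains[i] + 0.2
                                                : gains[i] * 0.8;
      if (gains[i] < 0.01) gains[i] = 0.01;
      uY[i] = momentum * uY[i] - learning_rate * gains[i] * grad[i];
    }
    for (int i = 0; i < n; ++i) {
      Y(i, 0) += uY[2 * i];
      Y(i, 1) += uY[2 * i + 1];
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}
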