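#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Brute-force k nearest neighbors of each row of Q among the rows of X.
// Returns 1-based indices and Euclidean distances, sorted ascending.
// [[Rcpp::export]]
List knn_brute(NumericMatrix X, NumericMatrix Q, int k) {
  const int n = X.nrow(), q = Q.nrow(), d = X.ncol();
  if (Q.ncol() != d) stop("dimension mismatch");
  if (k > n) stop("k exceeds the number of reference points");
  IntegerMatrix idx(q, k);
  NumericMatrix dist(q, k);
  std::vector<std::pair<double, int>> cand(n);
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double diff = Q(i, c) - X(j, c);
        s += diff * diff;
      }
      cand[j] = {s, j};
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;
      dist(i, j) = std::sqrt(cand[j].first);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Classic DBSCAN with O(n^2) region queries. Labels: 0 = outlier/noise,
// 1..n_clusters otherwise.
// [[Rcpp::export]]
IntegerVector dbscan_label(NumericMatrix X, double eps, int min_samples) {
  const int n = X.nrow(), d = X.ncol();
  const double eps2 = eps * eps;
  IntegerVector label(n, -1);  // -1 = unvisited
  std::vector<int> nbr;

  auto region = [&](int i, std::vector<int>& out) {
    out.clear();
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
        if (s > eps2) break;
      }
      if (s <= eps2) out.push_back(j);
    }
  };

  int cl = 0;
  std::vector<int> seeds, sub;
  for (int i = 0; i < n; ++i) {
    if (label[i] != -1) continue;
    region(i, nbr);
    if ((int)nbr.size() < min_samples) { label[i] = 0; continue; }
    ++cl;
    label[i] = cl;
    seeds.assign(nbr.begin(), nbr.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      int j = seeds[s];
      if (label[j] == 0) label[j] = cl;        // border point
      if (label[j] != -1) continue;
      label[j] = cl;
      region(j, sub);
      if ((int)sub.size() >= min_samples)
        seeds.insert(seeds.end(), sub.begin(), sub.end());
      Rcpp::checkUserInterrupt();
    }
  }
  return label;
}
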