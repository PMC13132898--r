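// Gradient boosting for binary classification with logistic loss:
// depth-wise regression trees fit to residuals (y - p), split on weighted
// variance reduction, Newton leaf values sum(r) / sum(p(1-p)), shrinkage by
// the learning rate. Mirrors the classical Friedman algorithm (and the
// defaults of the common Python implementation: min_samples_split = 2,
// min_samples_leaf = 1, midpoint thresholds, features scanned in order with
// strict improvement required to switch the best split).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  double value;     // leaf value (already Newton-scaled, no learning rate)
  int left, right;
};

static void build_node(const NumericMatrix &X, const std::vector<double> &resid,
                       const std::vector<double> &hess,
                       std::vector<int> &idx, int lo, int hi, int depth,
                       int max_depth, std::vector<TreeNode> &nodes, int me) {
  const int n = hi - lo;
  double sum_r = 0.0, sum_h = 0.0;
  for (int t = lo; t < hi; ++t) {
    sum_r += resid[idx[t]];
    sum_h += hess[idx[t]];
  }
  // candidate leaf value
  nodes[me].value = sum_r / std::max(sum_h, 1e-12);
  nodes[me].feature = -1;
  if (depth >= max_depth || n < 2) return;

  const int p = X.ncol();
  double best_gain = -1.0;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int f = 0; f < p; ++f) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
    double sl = 0.0; // prefix residual sum
    for (int k = 0; k < n - 1; ++k) {
      sl += resid[ord[k]];
      double xv = X(ord[k], f), xn = X(ord[k + 1], f);
      if (xn <= xv) continue; // tied values: no split point here
      int nl = k + 1, nr = n - nl;
      double sr = sum_r - sl;
      // maximizing sl^2/nl + sr^2/nr  <=>  maximizing variance reduction
      double gain = sl * sl / nl + sr * sr / nr;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xv + xn);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo:hi) around the split, preserving relative order
  std::vector<int> left, right;
  left.reserve(n);
  right.reserve(n);
  for (int t = lo; t < hi; ++t) {
    if (X(idx[t], best_f) <= best_thr) left.push_back(idx[t]);
    else right.push_back(idx[t]);
  }
  if (left.empty() || right.empty()) return; // numerically degenerate
  for (size_t t = 0; t < left.size(); ++t) idx[lo + t] = left[t];
  for (size_t t = 0; t < right.size(); ++t) idx[lo + left.size() + t] = right[t];

  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1});
  nodes[me].left = (int)nodes.size() - 1;
  build_node(X, resid, hess, idx, lo, lo + (int)left.size(), depth + 1,
             max_depth, nodes, nodes[me].left);
  nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1});
  nodes[me].right = (int)nodes.size() - 1;
  build_node(X, resid, hess, idx, lo + (int)left.size(), hi, depth + 1,
             max_depth, nodes, nodes[me].right);
}

static double tree_predict_one(const NumericMatrix &nodes, int row,
                               const NumericVector &x) {
  int cur = 0;
  while ((int)nodes(cur, 0) >= 0) {
    int f = (int)nodes(cur, 0);
    cur = (x[f] <= nodes(cur, 1)) ? (int)nodes(cur, 3) : (int)nodes(cur, 4);
  }
  return nodes(cur, 2);
}

// [[Rcpp::export]]
List gbm_train_cpp(NumericMatrix X, NumericVector y, double learning_rate,
                   int n_estimators, int max_depth) {
  const int n = X.nrow();
  double pos = 0.0;
  for (int i = 0; i < n; ++i) pos += y[i];
  double pbar = std::min(std::max(pos / n, 1e-12), 1.0 - 1e-12);
  const double f0 = std::log(pbar / (1.0 - pbar));
  std::vector<double> F(n, f0), resid(n), hess(n);
  List trees(n_estimators);
  for (int m = 0; m < n_estimators; ++m) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      resid[i] = y[i] - p;
      hess[i] = p * (1.0 - p);
    }
    std::vector<TreeNode> nodes;
    nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1});
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build_node(X, resid, hess, idx, 0, n, 0, max_depth, nodes, 0);
    NumericMatrix nm(nodes.size(), 5); // feature, threshold, value, left, right
    for (size_t k = 0; k < nodes.size(); ++k) {
      nm(k, 0) = nodes[k].feature;
      nm(k, 1) = nodes[k].threshold;
      nm(k, 2) = nodes[k].value;
      nm(k, 3) = nodes[k].left;
      nm(k, 4) = nodes[k].right;
    }
    trees[m] = nm;
    for (int i = 0; i < n; ++i) {
      NumericVector xi = X(i, _);
      F[i] += learning_rate * tree_predict_one(nm, i, xi);
    }
  }
  return List::create(_["f0"] = f0, _["learning_rate"] = learning_rate,
                      _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector gbm_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const double f0 = as<double>(model["f0"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, f0);
  for (int m = 0; m < trees.size(); ++m) {
    NumericMatrix nm = trees[m];
    for (int i = 0; i < n; ++i) {
      NumericVector xi = X(i, _);
      out[i] += lr * tree_predict_one(nm, i, xi);
    }
  }
  // return probabilities
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
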