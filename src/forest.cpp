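// Regression random forest: bagged CART trees with variance-reduction splits.
// Uses R's RNG (unif_rand) so set.seed() gives bit-reproducible forests.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;    // -1 for leaf
  double threshold;
  int left, right;
  double value;   // leaf mean
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_leaf, max_depth;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_,
              int mtry_, int min_leaf_, int max_depth_)
    : X(X_), y(y_), mtry(mtry_), min_leaf(min_leaf_), max_depth(max_depth_) {}

  int build(std::vector<int>& idx, int begin, int end, int depth) {
    const int n = end - begin;
    double sum = 0.0;
    for (int i = begin; i < end; ++i) sum += y[idx[i]];
    const double mean = sum / n;

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});

    if (n < 2 * min_leaf || (max_depth > 0 && depth >= max_depth)) return me;
    bool constant = true;
    for (int i = begin + 1; i < end && constant; ++i)
      if (y[idx[i]] != y[idx[begin]]) constant = false;
    if (constant) return me;

    // sample mtry candidate features without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    const int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }

    double best_score = -1.0;
    int best_feat = -1, best_pos = -1;
    double best_thresh = 0.0;
    std::vector<int> work(idx.begin() + begin, idx.begin() + end);
    std::vector<int> best_order;

    for (int j = 0; j < k; ++j) {
      const int f = feats[j];
      std::sort(work.begin(), work.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;  // stable under ties -> deterministic
      });
      double left_sum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        left_sum += y[work[i]];
        const int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double xl = X(work[i], f), xr = X(work[i + 1], f);
        if (xl == xr) continue;  // can't split between equal values
        const double right_sum = sum - left_sum;
        const double score = left_sum * left_sum / nl + right_sum * right_sum / nr;
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_pos = nl;
          best_thresh = xl + (xr - xl) / 2.0;
          best_order = work;
        }
      }
    }
    if (best_feat < 0) return me;

    std::copy(best_order.begin(), best_order.end(), idx.begin() + begin);
    // re-partition around the threshold (best_order is sorted by best_feat)
    int l = build(idx, begin, begin + best_pos, depth + 1);
    int r = build(idx, begin + best_pos, end, depth + 1);
    nodes[me].feature = best_feat;
    nodes[me].threshold = best_thresh;
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int num_trees, int mtry,
                int min_leaf, int max_depth, bool bootstrap) {
  const int n = X.nrow();
  if (n < 1) stop("empty training set");
  if (y.size() != n) stop("length(y) != nrow(X)");
  List forest(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int pick = (int)(unif_rand() * n);
        if (pick >= n) pick = n - 1;
        idx[i] = pick;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeBuilder tb(X, y, mtry, min_leaf, max_depth);
    tb.build(idx, 0, n, 0);
    NumericMatrix m((int)tb.nodes.size(), 5);
    for (size_t i = 0; i < tb.nodes.size(); ++i) {
      m(i, 0) = tb.nodes[i].feature;
      m(i, 1) = tb.nodes[i].threshold;
      m(i, 2) = tb.nodes[i].left;
      m(i, 3) = tb.nodes[i].right;
      m(i, 4) = tb.nodes[i].value;
    }
    forest[t] = m;
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  if (T > 0) for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
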