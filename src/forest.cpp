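// Regression random forest: bootstrap-aggregated CART trees with random
// feature subsampling at each node (variance-reduction splits). Kept minimal
// on purpose — only what the biomass-prediction module needs. Uses R's RNG
// so results are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;
};

int build_node(const NumericMatrix &X, const NumericVector &y,
               std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
               Tree &tree) {
  int n = hi - lo;
  double sum = 0.0, sumsq = 0.0;
  for (int t = lo; t < hi; ++t) { sum += y[idx[t]]; sumsq += y[idx[t]] * y[idx[t]]; }
  double mean = sum / n;
  int node = tree.feature.size();
  tree.feature.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.value.push_back(mean);
  double sse = sumsq - sum * sum / n;
  if (n <= min_node || sse <= 1e-12) return node;

  int p = X.ncol();
  // partial Fisher-Yates for mtry candidate features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + (int)(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, double> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int t = 0; t < n; ++t)
      vals[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double lsum = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      lsum += vals[t].second;
      if (vals[t].first == vals[t + 1].first) continue;
      int nl = t + 1, nr = n - nl;
      double rsum = sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_feat) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tree.feature[node] = best_feat;
  tree.thr[node] = best_thr;
  int l = build_node(X, y, idx, lo, mid, mtry, min_node, tree);
  tree.left[node] = l;
  int r = build_node(X, y, idx, mid, hi, mtry, min_node, tree);
  tree.right[node] = r;
  return node;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_node) {
  RNGScope scope;
  int n = X.nrow();
  List forest(n_trees);
  std::vector<int> idx(n);
  for (int b = 0; b < n_trees; ++b) {
    for (int t = 0; t < n; ++t) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[t] = r;
    }
    Tree tree;
    build_node(X, y, idx, 0, n, mtry, min_node, tree);
    forest[b] = List::create(_["feature"] = wrap(tree.feature),
                             _["thr"] = wrap(tree.thr),
                             _["left"] = wrap(tree.left),
                             _["right"] = wrap(tree.right),
                             _["value"] = wrap(tree.value));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = forest[b];
    IntegerVector feature = tr["feature"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out / (double)B;
}
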