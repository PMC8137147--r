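// Minimal classification random forest (gini impurity, bootstrap samples,
// random feature subsets, trees grown to purity). Uses R's RNG so results
// are reproducible under set.seed(). Intended for the small feature tables
// of the lab-membership analysis, where leave-one-out cross-validation over
// thousands of subsample repeats makes a pure-R forest infeasible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right, pred;
};

double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) {
    double p = (double)c / n;
    g -= p * p;
  }
  return g;
}

int grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y, int K,
         std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
         int depth) {
  int n = hi - lo;
  std::vector<int> cnt(K, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[maj]) maj = k;
  bool pure = cnt[maj] == n;

  int node = tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(maj);
  if (pure || n <= min_node || depth > 64) return node;

  int d = X.ncol();
  // sample mtry features without replacement
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    int pick = j + (int)(unif_rand() * (d - j));
    if (pick >= d) pick = d - 1;
    std::swap(feats[j], feats[pick]);
  }

  double best_score = 1e18, best_thr = 0.0;
  int best_feat = -1;
  std::vector<double> vals(n);
  std::vector<int> ord(n), cl(K), cr(K);
  for (int jj = 0; jj < mtry; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i) { vals[i] = X(idx[lo + i], f); ord[i] = i; }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return vals[a] < vals[b]; });
    std::fill(cl.begin(), cl.end(), 0);
    for (int k = 0; k < K; ++k) cr[k] = cnt[k];
    for (int i = 0; i < n - 1; ++i) {
      int lab = y[idx[lo + ord[i]]];
      cl[lab]++; cr[lab]--;
      if (vals[ord[i + 1]] <= vals[ord[i]]) continue;  // tied values
      int nl = i + 1, nr = n - nl;
      double score = nl * gini_from_counts(cl, nl) +
                     nr * gini_from_counts(cr, nr);
      if (score < best_score) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (vals[ord[i]] + vals[ord[i + 1]]);
      }
    }
  }
  if (best_feat < 0) return node;  // no valid split (all features constant)

  // partition idx[lo,hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  int l = grow(tree, X, y, K, idx, lo, mid, mtry, min_node, depth + 1);
  tree.left[node] = l;
  int r = grow(tree, X, y, K, idx, mid, hi, mtry, min_node, depth + 1);
  tree.right[node] = r;
  return node;
}

List pack(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["pred"] = wrap(t.pred));
}

int predict_one(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"],
                pred = tree["pred"];
  int node = 0;
  while (feature[node] >= 0) {
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  }
  return pred[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_class, int n_tree,
                  int mtry, int min_node) {
  RNGScope scope;
  int n = X.nrow();
  List trees(n_tree);
  std::vector<int> idx(n);
  for (int t = 0; t < n_tree; ++t) {
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    Tree tree;
    grow(tree, X, y, n_class, idx, 0, n, mtry, min_node, 0);
    trees[t] = pack(tree);
  }
  return trees;
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List trees, NumericMatrix X, int n_class) {
  int n = X.nrow(), T = trees.size();
  IntegerVector out(n);
  std::vector<int> votes(n_class);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < T; ++t) votes[predict_one(trees[t], X, i)]++;
    out[i] = (int)(std::max_element(votes.begin(), votes.end()) -
                   votes.begin());
  }
  return out;
}
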