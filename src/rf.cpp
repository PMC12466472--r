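// Compact random-forest classifier used for driver-genus ranking.
// Trees: CART with Gini impurity, mtry feature subsampling, bootstrap
// resampling. Randomness comes from R's RNG (via unif_rand) so set.seed()
// on the R side makes forests reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf class
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int majority(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;
  return best;
}

int grow(Tree& T, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
         int nclass, std::vector<int>& featbuf) {
  int n = hi - lo;
  std::vector<int> cnt(nclass, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int node = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.pred.push_back(majority(cnt));
  bool pure = false;
  for (int c = 0; c < nclass; ++c) if (cnt[c] == n) pure = true;
  if (n <= min_node || pure) return node;

  // sample mtry distinct features (partial Fisher-Yates)
  int p = X.ncol();
  for (int j = 0; j < p; ++j) featbuf[j] = j;
  int best_f = -1; double best_thr = 0.0, best_gain = 1e-12;
  double parent_imp = 1.0;
  for (int c = 0; c < nclass; ++c) {
    double pr = (double)cnt[c] / n;
    parent_imp -= pr * pr;
  }
  parent_imp *= n;

  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> lcnt(nclass);
  for (int m = 0; m < mtry; ++m) {
    int pick = m + runif_int(p - m);
    std::swap(featbuf[m], featbuf[pick]);
    int f = featbuf[m];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      lcnt[vals[i].second]++;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      double il = 1.0, ir = 1.0;
      for (int c = 0; c < nclass; ++c) {
        double pl = (double)lcnt[c] / nl;
        double pr = (double)(cnt[c] - lcnt[c]) / nr;
        il -= pl * pl; ir -= pr * pr;
      }
      double gain = parent_imp - nl * il - nr * ir;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // degenerate, keep leaf
  T.feat[node] = best_f; T.thr[node] = best_thr;
  int l = grow(T, X, y, idx, lo, mid, mtry, min_node, nclass, featbuf);
  T.left[node] = l;
  int r = grow(T, X, y, idx, mid, hi, mtry, min_node, nclass, featbuf);
  T.right[node] = r;
  return node;
}

int predict_tree(const Tree& T, const NumericMatrix& X, int row,
                 const std::vector<double>* override_col, int override_f) {
  int node = 0;
  while (T.feat[node] >= 0) {
    int f = T.feat[node];
    double v = (override_col && f == override_f) ? (*override_col)[row]
                                                 : X(row, f);
    node = (v <= T.thr[node]) ? T.left[node] : T.right[node];
  }
  return T.pred[node];
}

double forest_accuracy(const std::vector<Tree>& forest,
                       const NumericMatrix& Xte, const IntegerVector& yte,
                       int nclass, const std::vector<double>* override_col,
                       int override_f) {
  int n = Xte.nrow(), correct = 0;
  std::vector<int> votes(nclass);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (size_t t = 0; t < forest.size(); ++t)
      votes[predict_tree(forest[t], Xte, i, override_col, override_f)]++;
    if (majority(votes) == yte[i]) correct++;
  }
  return (double)correct / n;
}

} // namespace

// [[Rcpp::export]]
List rf_cv_importance(NumericMatrix Xtr, IntegerVector ytr,
                      NumericMatrix Xte, IntegerVector yte,
                      int ntree, int mtry, int min_node, int nclass) {
  int n = Xtr.nrow(), p = Xtr.ncol();
  std::vector<Tree> forest(ntree);
  std::vector<int> idx(n), featbuf(p);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n);  // bootstrap
    grow(forest[t], Xtr, ytr, idx, 0, n, mtry, min_node, nclass, featbuf);
  }
  double base = forest_accuracy(forest, Xte, yte, nclass, 0, -1);
  // Breiman-style permutation importance: per-tree accuracy drop on the
  // held-out set, averaged over trees (robust to redundant features, which
  // leave whole-forest accuracy unchanged).
  int m = Xte.nrow();
  std::vector<double> tree_base(ntree);
  for (int t = 0; t < ntree; ++t) {
    int correct = 0;
    for (int i = 0; i < m; ++i)
      if (predict_tree(forest[t], Xte, i, 0, -1) == yte[i]) correct++;
    tree_base[t] = (double)correct / m;
  }
  NumericVector importance(p);
  std::vector<double> col(m);
  std::vector<int> perm(m);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < m; ++i) perm[i] = i;
    for (int i = m - 1; i > 0; --i) std::swap(perm[i], perm[runif_int(i + 1)]);
    for (int i = 0; i < m; ++i) col[i] = Xte(perm[i], f);
    double drop = 0.0;
    for (int t = 0; t < ntree; ++t) {
      int correct = 0;
      for (int i = 0; i < m; ++i)
        if (predict_tree(forest[t], Xte, i, &col, f) == yte[i]) correct++;
      drop += tree_base[t] - (double)correct / m;
    }
    importance[f] = drop / ntree;
  }
  return List::create(_["accuracy"] = base, _["importance"] = importance);
}
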