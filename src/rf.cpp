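#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>
using namespace Rcpp;

// Classification random forest: CART trees, gini impurity, bootstrap
// resampling, mtry features per node, grown to purity by default.
// Trees are returned as flat node tables (feature, threshold, left,
// right, class-1 fraction) so prediction can rerun without refitting.
// All randomness comes from R's RNG (reproducible under set.seed()).

struct TreeNodes {
  std::vector<double> feat, thr, left, right, val;
};

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     std::vector<int> &samp, int lo, int hi, int mtry,
                     int min_node, TreeNodes &T) {
  const int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.val.push_back(0);

  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[samp[i]];
  T.val[node] = (double)n1 / n;
  if (n1 == 0 || n1 == n || n < 2 * min_node || n < 2) return node;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {  // partial Fisher-Yates
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  const double p1 = (double)n1 / n;
  const double g_parent = 2.0 * p1 * (1.0 - p1);
  double best_gain = 1e-12, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double, int> > v(n);
  for (int m = 0; m < mtry; ++m) {
    const int f = feats[m];
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(samp[lo + i], f), (int)y[samp[lo + i]]);
    std::sort(v.begin(), v.end());
    int ln = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      ++ln;
      l1 += v[i].second;
      if (v[i].first == v[i + 1].first) continue;
      const int rn = n - ln, r1 = n1 - l1;
      const double pl = (double)l1 / ln, pr = (double)r1 / rn;
      const double gain =
          g_parent - ((double)ln / n) * 2.0 * pl * (1.0 - pl) -
          ((double)rn / n) * 2.0 * pr * (1.0 - pr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = (v[i].first + v[i + 1].first) / 2.0;
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(samp[i], best_f) <= best_thr) std::swap(samp[mid++], samp[i]);
  if (mid == lo || mid == hi) return node;  // defensive; cannot happen

  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  T.left[node] = grow_node(X, y, samp, lo, mid, mtry, min_node, T);
  T.right[node] = grow_node(X, y, samp, mid, hi, mtry, min_node, T);
  return node;
}

// [[Rcpp::export]]
List rf_grow(NumericMatrix X, IntegerVector y, int ntree, int mtry,
             int min_node) {
  const int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> samp(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      samp[i] = k >= n ? n - 1 : k;
    }
    TreeNodes T;
    grow_node(X, y, samp, 0, n, mtry, min_node, T);
    const int m = (int)T.feat.size();
    NumericMatrix tr(m, 5);
    for (int i = 0; i < m; ++i) {
      tr(i, 0) = T.feat[i];
      tr(i, 1) = T.thr[i];
      tr(i, 2) = T.left[i];
      tr(i, 3) = T.right[i];
      tr(i, 4) = T.val[i];
    }
    forest[t] = tr;
  }
  return forest;
}

// Probability of class 1 = fraction of trees voting 1 (leaf ties 0.5).
// [[Rcpp::export]]
NumericVector rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector votes(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr(node, 0) >= 0)
        node = (X(i, (int)tr(node, 0)) <= tr(node, 1)) ? (int)tr(node, 2)
                                                       : (int)tr(node, 3);
      const double p1 = tr(node, 4);
      votes[i] += (p1 > 0.5) ? 1.0 : (p1 == 0.5 ? 0.5 : 0.0);
    }
  }
  for (int i = 0; i < n; ++i) votes[i] /= ntree;
  return votes;
}
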