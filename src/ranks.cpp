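#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Column-wise midranks plus the tie information needed by the rank-sum
// normal approximation: tie_term[j] = sum over tied groups of (t^3 - t).
// [[Rcpp::export]]
List col_ranks_ties(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix ranks(n, p);
  NumericVector tie_term(p);
  LogicalVector has_ties(p);
  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column col = x(_, j);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    double tt = 0.0;
    bool ties = false;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[idx[k + 1]] == col[idx[i]]) ++k;
      const double r = (i + k) / 2.0 + 1.0;
      for (int m = i; m <= k; ++m) ranks(idx[m], j) = r;
      const double t = k - i + 1;
      if (t > 1) { ties = true; tt += t * t * t - t; }
      i = k + 1;
    }
    tie_term[j] = tt;
    has_ties[j] = ties;
  }
  return List::create(_["ranks"] = ranks, _["tie_term"] = tie_term,
                      _["has_ties"] = has_ties);
}
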