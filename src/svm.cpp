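#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// C-SVC dual solver (simplified SMO, Platt 1998) on a precomputed kernel.
// y must be +1/-1. Uses R's RNG for the second-index choice, so results
// are reproducible under set.seed(). n here is small (tens of samples),
// hence the O(n) on-the-fly decision values instead of an error cache.
// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C, double tol,
               int max_passes) {
  const int n = K.nrow();
  NumericVector alpha(n);
  double b = 0.0;

  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0.0) s += alpha[j] * y[j] * K(j, i);
    return s;
  };

  int passes = 0, sweeps = 0;
  const int max_sweeps = 20000;
  while (passes < max_passes && sweeps < max_sweeps) {
    int num_changed = 0;
    for (int i = 0; i < n; ++i) {
      const double Ei = fx(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0.0)) {
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        if (j < 0) j = 0;
        if (j >= n) j = n - 1;
        const double Ej = fx(j) - y[j];
        const double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        const double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0.0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-6) continue;
        const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        const double b1 = b - Ei - y[i] * (ai - ai_old) * K(i, i) -
                          y[j] * (aj - aj_old) * K(i, j);
        const double b2 = b - Ej - y[i] * (ai - ai_old) * K(i, j) -
                          y[j] * (aj - aj_old) * K(j, j);
        if (ai > 0.0 && ai < C) b = b1;
        else if (aj > 0.0 && aj < C) b = b2;
        else b = (b1 + b2) / 2.0;
        ++num_changed;
      }
    }
    ++sweeps;
    if (num_changed == 0) ++passes; else passes = 0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b);
}
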