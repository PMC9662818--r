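#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft-margin linear SVM trained by sequential minimal optimization
// (Platt-style pair updates, deterministic second-choice heuristic).
// Problem sizes here are tiny (18 training trials), so no caching or
// shrinking is needed.  Returns the primal weight vector and bias.
// [[Rcpp::export]]
List cpp_svm_linear(NumericMatrix X, NumericVector y, double C = 1.0,
                    double tol = 1e-4, int max_sweeps = 500) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("label length mismatch");

  // linear kernel matrix
  std::vector<double> K(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
      K[i * n + j] = K[j * n + i] = s;
    }

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0.0) s += alpha[j] * y[j] * K[j * n + i];
    return s;
  };

  int sweep = 0;
  while (sweep < max_sweeps) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      const double Ei = fx(i) - y[i];
      const bool viol = (y[i] * Ei < -tol && alpha[i] < C) ||
                        (y[i] * Ei > tol && alpha[i] > 0.0);
      if (!viol) continue;
      // second index: largest |Ei - Ej|, deterministic
      int j = -1; double best = -1.0;
      for (int jj = 0; jj < n; ++jj) {
        if (jj == i) continue;
        double Ej = fx(jj) - y[jj];
        double gap = std::fabs(Ei - Ej);
        if (gap > best) { best = gap; j = jj; }
      }
      if (j < 0) continue;
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
      const double eta = 2.0 * K[i * n + j] - K[i * n + i] - K[j * n + j];
      if (eta >= 0.0) continue;
      double aj = aj_old - y[j] * (Ei - Ej) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      alpha[i] = ai; alpha[j] = aj;
      const double b1 = b - Ei - y[i] * (ai - ai_old) * K[i * n + i]
                        - y[j] * (aj - aj_old) * K[i * n + j];
      const double b2 = b - Ej - y[i] * (ai - ai_old) * K[i * n + j]
                        - y[j] * (aj - aj_old) * K[j * n + j];
      if (ai > 0.0 && ai < C) b = b1;
      else if (aj > 0.0 && aj < C) b = b2;
      else b = (b1 + b2) / 2.0;
      ++changed;
    }
    ++sweep;
    if (changed == 0) break;
  }

  NumericVector w(d);
  for (int k = 0; k < d; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += alpha[i] * y[i] * X(i, k);
    w[k] = s;
  }
  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["sweeps"] = sweep);
}
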