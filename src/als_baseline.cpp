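#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric least squares baselines for a matrix of spectra (one spectrum
// per column). Each iteration solves (W + lambda * D2' D2) z = W y, a
// pentadiagonal SPD system, by a banded LDL' factorization (bandwidth 2),
// then updates the asymmetric weights: p above the baseline, 1 - p below.
// Returns the fitted baselines (same shape as Y).

static inline double d2_entry(int row, int col) {
  // D2 row k has entries 1, -2, 1 at columns k, k+1, k+2
  int o = col - row;
  return o == 0 ? 1.0 : (o == 1 ? -2.0 : (o == 2 ? 1.0 : 0.0));
}

// [[Rcpp::export]]
NumericMatrix als_baseline_cpp(NumericMatrix Y, double lambda, double p, int maxit) {
  const int n = Y.nrow(), m = Y.ncol();
  NumericMatrix Z(n, m);
  if (n < 4) stop("need at least 4 samples");

  // constant penalty bands of lambda * D2'D2
  std::vector<double> d0(n), d1(n - 1), d2(n - 2);
  for (int i = 0; i < n; i++) {
    double v = 0;
    for (int k = std::max(0, i - 2); k <= std::min(i, n - 3); k++)
      v += d2_entry(k, i) * d2_entry(k, i);
    d0[i] = lambda * v;
  }
  for (int i = 0; i < n - 1; i++) {
    double v = 0;
    for (int k = std::max(0, i - 2); k <= std::min(i, n - 3); k++)
      v += d2_entry(k, i) * d2_entry(k, i + 1);
    d1[i] = lambda * v;
  }
  for (int i = 0; i < n - 2; i++) d2[i] = lambda;

  std::vector<double> w(n), l0(n), l1(n), l2(n), z(n), rhs(n);
  for (int col = 0; col < m; col++) {
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < maxit; it++) {
      // banded LDL' of (diag(w) + penalty): unit lower bands l1, l2, pivot l0
      for (int i = 0; i < n; i++) {
        double di = d0[i] + w[i];
        if (i >= 1) di -= l1[i - 1] * l1[i - 1] * l0[i - 1];
        if (i >= 2) di -= l2[i - 2] * l2[i - 2] * l0[i - 2];
        l0[i] = di;
        if (i < n - 1) {
          double e = d1[i];
          if (i >= 1) e -= l1[i - 1] * l2[i - 1] * l0[i - 1];
          l1[i] = e / di;
        }
        if (i < n - 2) l2[i] = d2[i] / di;
      }
      for (int i = 0; i < n; i++) rhs[i] = w[i] * Y(i, col);
      // forward L u = rhs
      for (int i = 0; i < n; i++) {
        double s = rhs[i];
        if (i >= 1) s -= l1[i - 1] * z[i - 1];
        if (i >= 2) s -= l2[i - 2] * z[i - 2];
        z[i] = s;
      }
      for (int i = 0; i < n; i++) z[i] /= l0[i];
      // backward L' z = u
      for (int i = n - 1; i >= 0; i--) {
        double s = z[i];
        if (i < n - 1) s -= l1[i] * z[i + 1];
        if (i < n - 2) s -= l2[i] * z[i + 2];
        z[i] = s;
      }
      bool changed = false;
      for (int i = 0; i < n; i++) {
        double wn = (Y(i, col) > z[i]) ? p : 1.0 - p;
        if (wn != w[i]) { w[i] = wn; changed = true; }
      }
      if (!changed) break;
    }
    for (int i = 0; i < n; i++) Z(i, col) = z[i];
  }
  return Z;
}
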