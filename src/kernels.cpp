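#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention).
// Unordered pairs i < j are counted over the first n - m template starts so
// that every length-m template has a length-(m+1) extension; both counts then
// share the same normalisation and the constant cancels in the ratio.
// Self-matches are excluded by construction. Chebyshev (max-norm) distance,
// match when the distance is <= r.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;
  if (nt < 2) {
    return List::create(_["a"] = 0.0, _["b"] = 0.0,
                        _["n_templates"] = std::max(nt, 0));
  }
  const double *p = REAL(x);
  double a = 0.0, b = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        b += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) <= r) a += 1.0;
      }
    }
  }
  return List::create(_["a"] = a, _["b"] = b, _["n_templates"] = nt);
}

// Exact two-sided permutation p-value for the Spearman correlation of the
// (mid-)rank vectors rx, ry: full enumeration of the n! orderings of ry.
// The statistic enumerated is |sum rx_i * ry_perm(i) - n * mean(rx) * mean(ry)|,
// a strictly increasing transform of |rho| for fixed marginals.
// [[Rcpp::export]]
double spearman_perm_p_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double t_obs = std::fabs(s_obs - n * mx * my);
  const double eps = 1e-9;
  double count = 0.0, total = 0.0;
  std::sort(idx.begin(), idx.end());
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * ry[idx[i]];
    if (std::fabs(s - n * mx * my) >= t_obs - eps) count += 1.0;
    total += 1.0;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return count / total;
}
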