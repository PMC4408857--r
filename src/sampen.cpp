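#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Raw match counts feeding the sample-entropy ratio: unordered template
// pairs within tolerance r at template lengths m (templates 1..N-m) and
// m+1 (templates 1..N-m-1).
//
// Both levels are counted in a single pass: an (m+1)-level match implies an
// m-level match on the same index pair (the distance over the first m
// coordinates cannot exceed the distance over m+1), so each candidate pair
// is tested at length m and, when both templates are valid at length m+1,
// extended by one coordinate.  Pruning: indices are sorted by the first
// coordinate, and any match requires |x_i - x_k| <= r there, so only a
// sliding window of the sorted order is scanned.  Counts are integers, so
// the result is exactly the brute-force double-loop count.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector xr, int m, double r,
                                bool chebyshev) {
  const int n = xr.size();
  const int imax_m = n - m;       // templates valid at length m (0-based < imax_m)
  const int imax_m1 = n - m - 1;  // templates valid at length m + 1
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<int> idx(imax_m);
  for (int i = 0; i < imax_m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  const double r2 = r * r;
  long long cm = 0, cm1 = 0;
  for (int a = 0; a < imax_m; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < imax_m; ++b) {
      const int k = idx[b];
      if (x[k] - x[i] > r) break;  // sorted: no later b can match
      if (chebyshev) {
        bool match = true;
        for (int j = 0; j < m; ++j) {
          if (std::fabs(x[i + j] - x[k + j]) > r) { match = false; break; }
        }
        if (!match) continue;
        ++cm;
        if (i < imax_m1 && k < imax_m1 &&
            std::fabs(x[i + m] - x[k + m]) <= r)
          ++cm1;
      } else {
        double s = 0.0;
        int j = 0;
        for (; j < m; ++j) {
          const double dj = x[i + j] - x[k + j];
          s += dj * dj;
          if (s > r2) break;
        }
        if (j < m) continue;
        ++cm;
        if (i < imax_m1 && k < imax_m1) {
          const double dm = x[i + m] - x[k + m];
          if (s + dm * dm <= r2) ++cm1;
        }
      }
    }
  }
  return NumericVector::create(static_cast<double>(cm),
                               static_cast<double>(cm1));
}
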