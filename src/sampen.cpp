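#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-pair counts for sample entropy.
// B = number of unordered template pairs of length m whose Chebyshev
// distance is <= r; A = same at length m + 1. Self-matches excluded; both
// counts run over the n - m templates starting at 0 .. n - m - 1
// (Richman & Moorman convention).
//
// Pairs are enumerated after sorting template start indices by their first
// sample: only pairs whose first coordinates already lie within r need the
// remaining coordinates checked, which prunes the O(n^2) scan by the
// per-coordinate matching probability.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-m templates considered
  double A = 0.0, B = 0.0;
  if (nt < 2) return NumericVector::create(A, B);

  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  for (int ii = 0; ii < nt; ++ii) {
    const int i = ord[ii];
    const double xi = x[i];
    for (int jj = ii + 1; jj < nt; ++jj) {
      const int j = ord[jj];
      if (x[j] - xi > r) break;  // sorted: no further first-coord match
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        double diff = x[i + k] - x[j + k];
        if (diff < 0) diff = -diff;
        if (diff > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double diff = x[i + m] - x[j + m];
      if (diff < 0) diff = -diff;
      if (diff <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
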