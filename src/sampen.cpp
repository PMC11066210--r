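#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman & Moorman).
// Templates of length m start at i = 0..n-m-1, so every length-m template
// also has a length-(m+1) extension. B counts unordered pairs within
// Chebyshev distance r at length m, A the same pairs still within r at
// length m+1. Self-matches are excluded.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
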