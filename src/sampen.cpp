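#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample-entropy template match counts (Richman & Moorman convention):
// templates of length m and m+1 both start at i = 0..n-m-1 so the two
// counts are over the same index set; Chebyshev distance; non-strict
// tolerance (d <= r); self-matches excluded. Returns ordered-pair counts
// c(B_m, A_m1).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(const NumericVector& x, const int m, const double r) {
  const int n = x.size();
  if (n < m + 2) stop("series too short for embedding length m");
  const int nt = n - m;  // number of comparable template positions
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        // (m+1)-template distance is max of the m-template distance and
        // the one extra coordinate, so only that coordinate needs checking
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  // ordered-pair counts (i != j): each unordered match counts twice
  return NumericVector::create(2.0 * B, 2.0 * A);
}
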