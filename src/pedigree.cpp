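#include <Rcpp.h>
using namespace Rcpp;

// Numerator relationship matrix by the tabular method (full recursion, no
// inbreeding shortcut). sire/dam are 1-based indices into the pedigree order,
// 0 for unknown; parents must precede offspring (validated in R).
// [[Rcpp::export]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A(s, d);
    A(i, i) = aii;
  }
  return A;
}
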