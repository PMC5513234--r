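#include <Rcpp.h>
using namespace Rcpp;

// Pairwise difference / comparable-site counts for an integer-coded alignment.
// `codes` is sites x sequences (column-contiguous per sequence); values 0..3
// are A,C,G,T and any negative value is missing (gap, N, IUPAC ambiguity).
// Pairwise deletion: a column counts for a pair only when both entries are
// in 0..3.
// [[Rcpp::export]]
List pair_diff_counts(IntegerMatrix codes) {
  const int L = codes.nrow(), n = codes.ncol();
  IntegerMatrix diff(n, n), valid(n, n);
  for (int i = 0; i < n; ++i) {
    const int *ci = &codes(0, i);
    for (int j = i + 1; j < n; ++j) {
      const int *cj = &codes(0, j);
      int d = 0, v = 0;
      for (int k = 0; k < L; ++k) {       // branch-free so the loop vectorizes
        const int a = ci[k], b = cj[k];
        const int ok = (a >= 0) & (b >= 0);
        v += ok;
        d += ok & (a != b);
      }
      diff(i, j) = d; diff(j, i) = d;
      valid(i, j) = v; valid(j, i) = v;
    }
  }
  return List::create(_["diff"] = diff, _["valid"] = valid);
}
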