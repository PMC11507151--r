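#include <Rcpp.h>
using namespace Rcpp;

// Ordinal (Bandt-Pompe) pattern ids for all overlapping embedded vectors
// x_t, x_{t+tau}, ..., x_{t+(D-1)tau}. Each vector is mapped to the
// lexicographic rank (0-based) of the permutation that sorts it ascending,
// ties broken by temporal order (earlier sample ranks lower).
// [[Rcpp::export]]
IntegerVector ord_pattern_ids_cpp(NumericVector x, int D, int tau) {
  const int M = x.size();
  const int n = M - (D - 1) * tau;
  if (n < 1) stop("series too short for the requested embedding");
  IntegerVector ids(n);
  std::vector<int> rank(D), perm(D), fact(D);
  fact[D - 1] = 1;
  for (int i = D - 2; i >= 0; --i) fact[i] = fact[i + 1] * (D - 1 - i);
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < D; ++i) {
      const double xi = x[t + i * tau];
      int r = 0;
      for (int j = 0; j < D; ++j) {
        if (j == i) continue;
        const double xj = x[t + j * tau];
        if (xj < xi || (xj == xi && j < i)) ++r;
      }
      rank[i] = r;
    }
    for (int i = 0; i < D; ++i) perm[rank[i]] = i;
    int id = 0;
    for (int i = 0; i < D - 1; ++i) {
      int c = 0;
      for (int j = i + 1; j < D; ++j)
        if (perm[j] < perm[i]) ++c;
      id += c * fact[i];
    }
    ids[t] = id;
  }
  return ids;
}
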