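#include <Rcpp.h>
using namespace Rcpp;

// Greedy one-to-one assignment: repeatedly match the globally closest
// (target, source) pair and retire both. Used by the spin permutation test
// to turn nearest-centroid reassignment under a random rotation into a true
// permutation, so each map's value multiset is preserved exactly.
// [[Rcpp::export(name = ".greedy_assign")]]
IntegerVector greedy_assign(NumericMatrix dist) {
  int n = dist.nrow();
  if (dist.ncol() != n) stop("distance matrix must be square");
  NumericMatrix d = clone(dist);
  IntegerVector out(n, NA_INTEGER);
  const double inf = R_PosInf;
  for (int step = 0; step < n; ++step) {
    double best = inf;
    int bi = -1, bj = -1;
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        double v = d(i, j);
        if (v < best) { best = v; bi = i; bj = j; }
      }
    }
    if (bi < 0) stop("no assignable pair left (non-finite distances?)");
    out[bi] = bj + 1;  // 1-based source index
    for (int j = 0; j < n; ++j) d(bi, j) = inf;
    for (int i = 0; i < n; ++i) d(i, bj) = inf;
  }
  return out;
}
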