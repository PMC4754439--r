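#include <Rcpp.h>
using namespace Rcpp;

// Natural visibility graph edges by the maximum-slope sweep.
//
// Nodes m < n are linked iff every intermediate sample lies STRICTLY below
// the chord from (m, x[m]) to (n, x[n]); equivalently, iff the slope
// (x[n] - x[m]) / (n - m) strictly exceeds the running maximum of the
// slopes (x[t] - x[m]) / (t - m) over m < t < n. A collinear intermediate
// point therefore blocks visibility. One forward sweep per anchor gives
// O(n^2) total work. The criterion involves only slope comparisons, so the
// graph is invariant under adding a constant to all values.
//
// Returns a 2-column integer matrix of 1-based (i, j) pairs with i < j.
// [[Rcpp::export(name = ".vg_edges_cpp")]]
IntegerMatrix vg_edges_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> ei, ej;
  ei.reserve(4 * n);
  ej.reserve(4 * n);
  for (int m = 0; m < n - 1; ++m) {
    double max_slope = R_NegInf;
    for (int j = m + 1; j < n; ++j) {
      double slope = (x[j] - x[m]) / (double)(j - m);
      if (j == m + 1 || slope > max_slope) {
        ei.push_back(m + 1);
        ej.push_back(j + 1);
      }
      if (slope > max_slope) max_slope = slope;
    }
  }
  const int ne = (int)ei.size();
  IntegerMatrix out(ne, 2);
  for (int k = 0; k < ne; ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}
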