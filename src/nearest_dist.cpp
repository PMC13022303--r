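#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to a reference point set.
// Brute force over the densified boundary points; contractually identical to
// exhaustive search (asserted against a pure-R oracle in the test suite).
// [[Rcpp::export(name = ".nearest_dist_cpp")]]
NumericVector nearest_dist_cpp(NumericVector px, NumericVector py,
                               NumericVector qx, NumericVector qy) {
  const R_xlen_t n = px.size(), m = qx.size();
  if (py.size() != n) stop("px and py lengths differ");
  if (qy.size() != m) stop("qx and qy lengths differ");
  if (m == 0) stop("reference point set is empty");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i];
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double dx = xi - qx[j], dy = yi - qy[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
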