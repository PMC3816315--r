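#include <Rcpp.h>
#include <vector>

// One Heavy Edge Matching sweep. Nodes are visited in `order`; each still
// unmatched node u scans its edge set in stored (descending weight) order,
// stops the scan when the edge weight drops below min_weight, skips matched
// neighbors and neighbors whose prospective supernode edge density is not
// strictly greater than min_density, and matches u to the first surviving
// neighbor. `match` holds the current partner (-1 if unmatched) and is
// updated in place across passes; `mweight` receives the matched edge weight.
//
// All node ids and offsets are 0-based; offsets has length n+1.
// [[Rcpp::export(name = ".hem_pass_cpp")]]
Rcpp::List hem_pass_cpp(const Rcpp::IntegerVector& offsets,
                        const Rcpp::IntegerVector& dst,
                        const Rcpp::NumericVector& weight,
                        const Rcpp::NumericVector& nw,
                        const Rcpp::NumericVector& ew,
                        const Rcpp::IntegerVector& order,
                        Rcpp::IntegerVector match,
                        Rcpp::NumericVector mweight,
                        double min_density, double min_weight) {
  for (int t = 0; t < order.size(); ++t) {
    const int u = order[t];
    if (match[u] >= 0) continue;
    for (int e = offsets[u]; e < offsets[u + 1]; ++e) {
      const double w = weight[e];
      if (w < min_weight) break;  // edge set sorted by descending weight
      const int v = dst[e];
      if (match[v] >= 0) continue;
      const double s = nw[u] + nw[v];
      const double dens = 2.0 * (ew[u] + ew[v] + w) / (s * (s - 1.0));
      if (!(dens > min_density)) continue;
      match[u] = v; match[v] = u;
      mweight[u] = w; mweight[v] = w;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("match") = match,
                            Rcpp::Named("mweight") = mweight);
}
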