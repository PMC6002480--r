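#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Binned ordered-pair sums for cumulative mark mingling statistics.
//
// For every ordered pair (i, j), i a reference tree, j any other tree, with
// ||x_i - x_j|| <= max(breaks), accumulates into the bin of the first grid
// distance >= the pair distance:
//   den: translation edge-correction weight w = A / ((a-|dx|)(b-|dy|))
//   num: w when the two trees carry different species marks
// Cumulative sums over bins (done in R) give the numerator and denominator
// of the mark mingling function at each grid distance; pair counts support
// undefined-value bookkeeping. breaks must be sorted ascending and strictly
// below min(a, b) so every admissible pair has a defined weight.
// [[Rcpp::export]]
List pair_bin_sums(NumericVector x, NumericVector y,
                   IntegerVector species, LogicalVector is_ref,
                   NumericVector breaks, double a, double b) {
  const int n = x.size();
  const int nb = breaks.size();
  const double rmax = nb > 0 ? breaks[nb - 1] : 0.0;
  const double rmax2 = rmax * rmax;
  const double area = a * b;
  NumericVector num(nb), den(nb);
  IntegerVector npairs(nb);
  const double* br = breaks.begin();
  for (int i = 0; i < n; ++i) {
    if (!is_ref[i]) continue;
    const double xi = x[i], yi = y[i];
    const int si = species[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi;
      const double dy = y[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      const double d = std::sqrt(d2);
      int bin = int(std::lower_bound(br, br + nb, d) - br);
      if (bin >= nb) bin = nb - 1;  // guards d == rmax under fp round-off
      const double w = area / ((a - std::fabs(dx)) * (b - std::fabs(dy)));
      den[bin] += w;
      npairs[bin] += 1;
      if (species[j] != si) num[bin] += w;
    }
  }
  return List::create(_["num"] = num, _["den"] = den, _["npairs"] = npairs);
}
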