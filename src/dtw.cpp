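#include <Rcpp.h>
using namespace Rcpp;

// Unnormalised dynamic time warping cost between two 1-D sequences with
// absolute-difference local cost, full alignment lattice (no window).
// step_weight is the weight of the diagonal transition: 1 for the
// "symmetric1" pattern, 2 for "symmetric2".
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, double step_weight) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m), curr(m);
  const double inf = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double c = std::abs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = c;  // origin cell carries its own local cost once
      } else {
        best = inf;
        if (i > 0) best = std::min(best, prev[j] + c);            // vertical
        if (j > 0) best = std::min(best, curr[j - 1] + c);        // horizontal
        if (i > 0 && j > 0)
          best = std::min(best, prev[j - 1] + step_weight * c);   // diagonal
      }
      curr[j] = best;
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}
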