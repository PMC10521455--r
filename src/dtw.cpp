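#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Normalized DTW by dynamic programming over monotone, continuous warping
// paths from (1,1) to (n,m). Step weights follow the index-step convention:
// symmetric form gives weight 2 to diagonal moves and 1 to horizontal /
// vertical ones (start cell weight 2, path weight total n + m); asymmetric
// form weights each step by the advance of the first series' index (start
// cell weight 1, total n). Cell cost is |y_i - z_j|. Because the weight
// total is path-independent, minimizing the weighted sum minimizes the
// normalized distance.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector y, NumericVector z, bool symmetric) {
  const int n = y.size(), m = z.size();
  const double INF = R_PosInf;
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double d = std::fabs(y[i] - z[j]);
      double best;
      if (i == 0 && j == 0) {
        best = symmetric ? 2.0 * d : d;
      } else {
        const double diag = (i > 0 && j > 0) ? prev[j - 1] : INF;
        const double up   = (i > 0) ? prev[j] : INF;   // advance Y only
        const double left = (j > 0) ? cur[j - 1] : INF; // advance Z only
        if (symmetric) {
          best = std::min(diag + 2.0 * d, std::min(up + d, left + d));
        } else {
          best = std::min(diag + d, std::min(up + d, left));
        }
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  const double norm = symmetric ? double(n + m) : double(n);
  return prev[m - 1] / norm;
}
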