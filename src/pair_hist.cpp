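#include <Rcpp.h>
using namespace Rcpp;

// Histogram of all pairwise Euclidean distances among (x, y), with n_bins
// bins of width bin_width starting at 0. Distances >= n_bins * bin_width are
// dropped. O(n^2) but allocation-free; used by the pair-correlation kernels.
// [[Rcpp::export]]
NumericVector pair_dist_hist(NumericVector x, NumericVector y,
                             double bin_width, int n_bins) {
  int n = x.size();
  NumericVector h(n_bins);
  double rmax = bin_width * n_bins;
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[j];
      if (dx > rmax || dx < -rmax) continue;
      double dy = yi - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      h[(int)(std::sqrt(d2) / bin_width)] += 1.0;
    }
  }
  return h;
}

// Histogram of cross distances between point sets (x1, y1) and (x2, y2).
// [[Rcpp::export]]
NumericVector cross_dist_hist(NumericVector x1, NumericVector y1,
                              NumericVector x2, NumericVector y2,
                              double bin_width, int n_bins) {
  int n1 = x1.size(), n2 = x2.size();
  NumericVector h(n_bins);
  double rmax = bin_width * n_bins;
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n1; ++i) {
    double xi = x1[i], yi = y1[i];
    for (int j = 0; j < n2; ++j) {
      double dx = xi - x2[j];
      if (dx > rmax || dx < -rmax) continue;
      double dy = yi - y2[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      h[(int)(std::sqrt(d2) / bin_width)] += 1.0;
    }
  }
  return h;
}
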