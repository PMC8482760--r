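// Local-maximum detection with topographic prominence and half-prominence
// widths, equivalent in spirit to MATLAB findpeaks(..., 'MinPeakProminence')
// but returning all candidates; thresholding happens in R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
Rcpp::DataFrame cpp_find_peaks(const Rcpp::NumericVector& x) {
  const int n = x.size();
  std::vector<int> idx;
  std::vector<double> prom, width, wl, wr;
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      // prominence: scan outwards until a higher point or the edge
      double lmin = x[i], rmin = x[i];
      for (int j = i - 1; j >= 0; --j) {
        if (x[j] > x[i]) break;
        if (x[j] < lmin) lmin = x[j];
      }
      for (int j = i + 1; j < n; ++j) {
        if (x[j] > x[i]) break;
        if (x[j] < rmin) rmin = x[j];
      }
      double p = x[i] - std::max(lmin, rmin);
      if (p <= 0) continue;
      // full width at half prominence, linear interpolation at crossings
      double level = x[i] - 0.5 * p;
      double li = 0, ri = n - 1;
      for (int j = i - 1; j >= 0; --j) {
        if (x[j] <= level) {
          li = j + (level - x[j]) / (x[j + 1] - x[j]);
          break;
        }
        if (j == 0) li = 0;
      }
      for (int j = i + 1; j < n; ++j) {
        if (x[j] <= level) {
          ri = j - (level - x[j]) / (x[j - 1] - x[j]);
          break;
        }
        if (j == n - 1) ri = n - 1;
      }
      idx.push_back(i + 1);  // 1-based for R
      prom.push_back(p);
      wl.push_back(li + 1);
      wr.push_back(ri + 1);
      width.push_back(ri - li);
    }
  }
  return DataFrame::create(Named("idx") = idx, Named("prominence") = prom,
                           Named("width_samples") = width,
                           Named("left") = wl, Named("right") = wr);
}
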