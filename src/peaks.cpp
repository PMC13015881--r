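#include <Rcpp.h>
using namespace Rcpp;

// Local maxima and topographic prominence of a discrete intensity sequence.
//
// A local maximum is a sample (or plateau of equal samples) with strictly
// lower neighbours on both sides; sequence edges never qualify. The
// prominence of a peak is its height minus the higher of the two saddle
// minima found by walking left and right until a strictly taller sample or
// the end of the sequence is reached (the scipy.signal convention).
//
// [[Rcpp::export(name = ".cpp_peak_prominences")]]
List cpp_peak_prominences(NumericVector y) {
  int n = y.size();
  std::vector<int> idx;
  std::vector<double> prom;
  int i = 1;
  while (i < n - 1) {
    if (y[i] > y[i - 1]) {
      int j = i;                      // plateau [i, j]
      while (j < n - 1 && y[j + 1] == y[i]) ++j;
      if (j < n - 1 && y[j + 1] < y[i]) {
        int mid = i + (j - i) / 2;
        double h = y[mid];
        // walk left
        double lmin = h;
        for (int k = i - 1; k >= 0; --k) {
          if (y[k] > h) break;
          if (y[k] < lmin) lmin = y[k];
        }
        // walk right
        double rmin = h;
        for (int k = j + 1; k < n; ++k) {
          if (y[k] > h) break;
          if (y[k] < rmin) rmin = y[k];
        }
        idx.push_back(mid + 1);       // 1-based for R
        prom.push_back(h - std::max(lmin, rmin));
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
  return List::create(_["index"] = wrap(idx), _["prominence"] = wrap(prom));
}
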