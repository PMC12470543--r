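#include <Rcpp.h>
using namespace Rcpp;

// Edge-preserving mean-shift intensity filter.
//
// For every pixel the intensity mode is sought iteratively: the running
// estimate is replaced by the mean of all window pixels whose intensity lies
// within rangeRadius of it, until the shift falls below 0.1 or maxIter is
// reached. Constant regions are fixed points, and steps larger than
// rangeRadius are never averaged across, which preserves cell/background
// boundaries while flattening staining texture.
// [[Rcpp::export(name = ".meanShiftCpp")]]
NumericMatrix meanShiftCpp(NumericMatrix img, int spatialRadius,
                           double rangeRadius, int maxIter) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double mode = img(i, j);
      for (int it = 0; it < maxIter; ++it) {
        double sum = 0.0;
        int cnt = 0;
        const int i0 = std::max(0, i - spatialRadius);
        const int i1 = std::min(nr - 1, i + spatialRadius);
        const int j0 = std::max(0, j - spatialRadius);
        const int j1 = std::min(nc - 1, j + spatialRadius);
        for (int jj = j0; jj <= j1; ++jj) {
          for (int ii = i0; ii <= i1; ++ii) {
            const double v = img(ii, jj);
            if (std::abs(v - mode) <= rangeRadius) {
              sum += v;
              ++cnt;
            }
          }
        }
        const double next = sum / cnt;  // cnt >= 1 (centre always qualifies)
        if (std::abs(next - mode) < 0.1) {
          mode = next;
          break;
        }
        mode = next;
      }
      out(i, j) = mode;
    }
  }
  return out;
}
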