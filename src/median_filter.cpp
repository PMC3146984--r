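#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 2-D median filter with replicated borders; window is odd.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int window) {
  const int half = window / 2, nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -half; dj <= half; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -half; di <= half; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[n++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
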