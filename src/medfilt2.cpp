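#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Reflect an out-of-range index into [0, n) (symmetric padding: the edge
// sample is repeated, matching half-sample mirror reflection).
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

//' 2D median filter with reflection padding (internal workhorse)
//'
//' @param x numeric matrix
//' @param window odd window side length
//' @noRd
// [[Rcpp::export]]
Rcpp::NumericMatrix medfilt2_cpp(Rcpp::NumericMatrix x, int window) {
  const int nr = x.nrow(), nc = x.ncol();
  const int hw = window / 2;
  const int wlen = window * window;
  Rcpp::NumericMatrix out(nr, nc);
  std::vector<double> buf(wlen);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -hw; dj <= hw; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -hw; di <= hw; ++di) {
          const int ii = reflect(i + di, nr);
          buf[k++] = x(ii, jj);
        }
      }
      // odd window*window, so the median is a single order statistic
      std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.end());
      out(i, j) = buf[wlen / 2];
    }
  }
  return out;
}
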