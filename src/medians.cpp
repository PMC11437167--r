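#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Row-wise median ignoring NA/NaN. Even counts give the mean of the two
// central values; all-NA rows give NA. Used for per-pixel seasonal
// compositing where the number of contributing passes varies by pixel.
// [[Rcpp::export]]
NumericVector rowMediansNA(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < k; ++j) {
      const double v = x(i, j);
      if (!ISNAN(v)) buf.push_back(v);
    }
    const int m = static_cast<int>(buf.size());
    if (m == 0) {
      out[i] = NA_REAL;
      continue;
    }
    std::sort(buf.begin(), buf.end());
    out[i] = (m % 2 == 1) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
  }
  return out;
}
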