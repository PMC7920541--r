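#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of a strided slice of length n. Operates on a scratch buffer so the
// input stays untouched.
static double strided_median(const double *x, R_xlen_t stride, int n,
                             std::vector<double> &buf) {
  for (int i = 0; i < n; ++i) buf[i] = x[(R_xlen_t)i * stride];
  int mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + n);
  double hi = buf[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return 0.5 * (lo + hi);
}

// Subtract, at every (trial, sample), the median across channels from each
// channel. `x` is a trials x channels x samples array (column-major).
// [[Rcpp::export]]
NumericVector cpp_median_reference(NumericVector x, int n_trials,
                                   int n_channels, int n_samples) {
  if ((R_xlen_t)n_trials * n_channels * n_samples != x.size())
    stop("dimensions do not match array length");
  NumericVector out = clone(x);
  double *p = REAL(out);
  std::vector<double> buf(n_channels);
  R_xlen_t tc = (R_xlen_t)n_trials * n_channels;
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < n_trials; ++t) {
      double *base = p + (R_xlen_t)s * tc + t;
      double med = strided_median(base, n_trials, n_channels, buf);
      for (int c = 0; c < n_channels; ++c)
        base[(R_xlen_t)c * n_trials] -= med;
    }
  }
  return out;
}
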