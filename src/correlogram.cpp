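#include <Rcpp.h>
using namespace Rcpp;

// Lagged coincidence sum: out[tau + L] = sum_t x[t] * y[t + tau], tau in -L..L.
// Out-of-range products contribute 0. Skips zero entries of x, so cost is
// O(nnz(x) * (2L+1)) — spike trains are sparse.
// [[Rcpp::export(name = ".cc_lagged")]]
NumericVector cc_lagged(NumericVector x, NumericVector y, int L) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (L < 1) stop("L must be >= 1");
  NumericVector out(2 * L + 1);
  for (int t = 0; t < n; ++t) {
    double xv = x[t];
    if (xv == 0.0) continue;
    int lo = std::max(-L, -t);
    int hi = std::min(L, n - 1 - t);
    for (int tau = lo; tau <= hi; ++tau) out[tau + L] += xv * y[t + tau];
  }
  return out;
}

// Same-length convolution with zero-padded edges. Output index t takes
// sum_k kern[k] * x[t - k + c] with centre c = floor((nk - 1) / 2).
// [[Rcpp::export(name = ".conv_same")]]
NumericVector conv_same(NumericVector x, NumericVector kern) {
  int n = x.size(), nk = kern.size();
  int c = (nk - 1) / 2;
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int k = 0; k < nk; ++k) {
      int j = t - k + c;
      if (j >= 0 && j < n) acc += kern[k] * x[j];
    }
    out[t] = acc;
  }
  return out;
}
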