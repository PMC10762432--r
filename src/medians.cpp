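#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline double median_of(std::vector<double>& buf) {
  const int n = buf.size();
  const int k = n / 2;
  std::nth_element(buf.begin(), buf.begin() + k, buf.end());
  double hi = buf[k];
  if (n % 2 == 1) return hi;
  // even n: median = mean of the two central order statistics
  double lo = *std::max_element(buf.begin(), buf.begin() + k);
  return 0.5 * (lo + hi);
}

// Per-sample medians of N consecutive rows for every start 1..nrow-N.
// Returns a (nrow - N) x ncol matrix; row m covers input rows m..m+N-1.
// [[Rcpp::export]]
NumericMatrix sliding_col_medians(const NumericMatrix& w, const int N) {
  const int n = w.nrow(), T = w.ncol();
  if (N < 2 || N > n) stop("N must satisfy 2 <= N <= nrow(w)");
  const int m = n - N;
  NumericMatrix out(m, T);
  if (m == 0) return out;
  std::vector<double> buf(N);
  for (int col = 0; col < T; ++col) {
    for (int s = 0; s < m; ++s) {
      for (int i = 0; i < N; ++i) buf[i] = w(s + i, col);
      out(s, col) = median_of(buf);
    }
  }
  return out;
}

// Per-sample median over all rows.
// [[Rcpp::export]]
NumericVector col_medians_cpp(const NumericMatrix& w) {
  const int n = w.nrow(), T = w.ncol();
  if (n < 1) stop("need at least one row");
  NumericVector out(T);
  std::vector<double> buf(n);
  for (int col = 0; col < T; ++col) {
    for (int i = 0; i < n; ++i) buf[i] = w(i, col);
    out[col] = median_of(buf);
  }
  return out;
}
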