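#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length n-1).
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  const int n = b.size();
  const int m = x.size();
  if (a.size() != n) stop("a and b must have equal length");
  if (zi.size() != n - 1) stop("zi must have length n - 1");
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  const double a0 = a[0];
  std::vector<double> bn(n), an(n);
  for (int j = 0; j < n; ++j) { bn[j] = b[j] / a0; an[j] = a[j] / a0; }
  for (int i = 0; i < m; ++i) {
    const double xi = x[i];
    const double yi = bn[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int j = 0; j < n - 2; ++j) {
      z[j] = bn[j + 1] * xi + z[j + 1] - an[j + 1] * yi;
    }
    if (n > 1) z[n - 2] = bn[n - 1] * xi - an[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
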