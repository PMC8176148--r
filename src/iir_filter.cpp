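#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter applied independently to every
// column (zero initial conditions). Coefficients must be normalized so
// a[0] == 1.
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(NumericVector b, NumericVector a,
                              NumericMatrix X) {
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix Y(n, m);
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0), z(ns > 0 ? ns : 1);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double b0 = bb[0];
  double* zp = z.data();
  const double* bp = bb.data();
  const double* ap = aa.data();
  for (int j = 0; j < m; ++j) {
    const double* x = &X(0, j);
    double* y = &Y(0, j);
    std::fill(z.begin(), z.end(), 0.0);
    if (ns == 0) {
      for (int t = 0; t < n; ++t) y[t] = b0 * x[t];
      continue;
    }
    for (int t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = b0 * xt + zp[0];
      for (int k = 0; k < ns - 1; ++k)
        zp[k] = bp[k + 1] * xt + zp[k + 1] - ap[k + 1] * yt;
      zp[ns - 1] = bp[ns] * xt - ap[ns] * yt;
      y[t] = yt;
    }
  }
  return Y;
}
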