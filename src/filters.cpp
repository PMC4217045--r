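#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients are normalized so that
// a[0] == 1 on entry (the caller enforces this).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}

// FIR convolution evaluated only at requested (1-based) output centres:
// y[m] = sum_k h[k] * x[idx[m] - (k - centre)], zero-padded at the edges.
// centre is the 1-based index of the tap aligned with idx[m].
// [[Rcpp::export(name = ".fir_at_cpp")]]
NumericVector fir_at_cpp(NumericVector x, NumericVector h, IntegerVector idx,
                         int centre) {
  int n = x.size(), L = h.size(), m = idx.size();
  NumericVector y(m);
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    int i0 = idx[j] - 1; // 0-based sample aligned with tap (centre-1)
    for (int k = 0; k < L; ++k) {
      int i = i0 - (k - (centre - 1));
      if (i >= 0 && i < n) acc += h[k] * x[i];
    }
    y[j] = acc;
  }
  return y;
}
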