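#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/ARMA filter: a(1) is assumed normalized
// to 1 by the caller. States beyond the filter order stay zero.
// [[Rcpp::export]]
NumericVector arma_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), w(nw, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + w[0];
    for (int j = 1; j < nw; ++j)
      w[j - 1] = w[j] + bb[j] * xi - aa[j] * yi;  // w[nw-1] stays 0
    y[i] = yi;
  }
  return y;
}
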