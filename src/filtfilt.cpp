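// Forward-backward IIR cascade with odd-reflection padding, applied in one
// call so long multichannel signals avoid repeated extension/reversal copies.
#include <Rcpp.h>

static void df2t_pass(const std::vector<double>& b, const std::vector<double>& a,
                      const std::vector<double>& zi, std::vector<double>& x,
                      bool reverse) {
  const int nz = (int) std::max(b.size(), a.size()) - 1;
  const int n = (int) x.size();
  // steady-state initial conditions scaled by the first processed sample
  const double x0 = reverse ? x[n - 1] : x[0];
  std::vector<double> z(nz, 0.0);
  for (int k = 0; k < nz; ++k) z[k] = zi[k] * x0;
  for (int i = 0; i < n; ++i) {
    const int t = reverse ? n - 1 - i : i;
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 0; k < nz - 1; ++k) z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * yt;
    if (nz > 0) z[nz - 1] = b[nz] * xt - a[nz] * yt;
    x[t] = yt;
  }
}

// [[Rcpp::export]]
Rcpp::NumericMatrix filtfilt_cascade_rows(const Rcpp::List& b_list,
                                          const Rcpp::List& a_list,
                                          const Rcpp::List& zi_list,
                                          const Rcpp::NumericMatrix& x,
                                          int pad) {
  const int nr = x.nrow(), nc = x.ncol();
  Rcpp::NumericMatrix y(nr, nc);
  const int ns = b_list.size();
  std::vector<std::vector<double>> bs(ns), as(ns), zis(ns);
  for (int s = 0; s < ns; ++s) {
    Rcpp::NumericVector bv = b_list[s], av = a_list[s], zv = zi_list[s];
    const int nk = std::max(bv.size(), av.size());
    bs[s].assign(nk, 0.0); as[s].assign(nk, 0.0); zis[s].assign(nk - 1, 0.0);
    for (int i = 0; i < bv.size(); ++i) bs[s][i] = bv[i] / av[0];
    for (int i = 0; i < av.size(); ++i) as[s][i] = av[i] / av[0];
    for (int i = 0; i < zv.size(); ++i) zis[s][i] = zv[i];
  }
  std::vector<double> ext(nc + 2 * pad);
  for (int r = 0; r < nr; ++r) {
    for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x(r, 0) - x(r, pad - i);
    for (int i = 0; i < nc; ++i) ext[pad + i] = x(r, i);
    for (int i = 0; i < pad; ++i) {
      ext[pad + nc + i] = 2.0 * x(r, nc - 1) - x(r, nc - 2 - i);
    }
    for (int s = 0; s < ns; ++s) {
      df2t_pass(bs[s], as[s], zis[s], ext, false);
      df2t_pass(bs[s], as[s], zis[s], ext, true);
    }
    for (int i = 0; i < nc; ++i) y(r, i) = ext[pad + i];
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector filtfilt_cascade(const Rcpp::List& b_list,
                                     const Rcpp::List& a_list,
                                     const Rcpp::List& zi_list,
                                     const Rcpp::NumericVector& x, int pad) {
  const int n = x.size();
  std::vector<double> ext(n + 2 * pad);
  for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) ext[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  for (int s = 0; s < b_list.size(); ++s) {
    Rcpp::NumericVector bv = b_list[s], av = a_list[s], zv = zi_list[s];
    const int nk = std::max(bv.size(), av.size());
    std::vector<double> b(nk, 0.0), a(nk, 0.0), zi(nk - 1, 0.0);
    for (int i = 0; i < bv.size(); ++i) b[i] = bv[i] / av[0];
    for (int i = 0; i < av.size(); ++i) a[i] = av[i] / av[0];
    for (int i = 0; i < zv.size(); ++i) zi[i] = zv[i];
    df2t_pass(b, a, zi, ext, false);
    df2t_pass(b, a, zi, ext, true);
  }
  Rcpp::NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = ext[pad + i];
  return y;
}
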