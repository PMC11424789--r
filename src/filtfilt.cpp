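#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// One IIR pass over time, all channels at once. X is channels x samples
// (column-major, so each sample's channel vector is contiguous); the
// fused inner loop over channels vectorises.
static void iir_cols(const arma::vec& b, const arma::vec& a, arma::mat& X) {
  const arma::uword nb = b.n_elem, na = a.n_elem, n = X.n_cols,
                    m = X.n_rows;
  arma::mat Y(m, n, arma::fill::zeros);
  const double a0 = a[0];
  for (arma::uword t = 0; t < n; ++t) {
    double* y = Y.colptr(t);
    const arma::uword kb = std::min<arma::uword>(nb - 1, t);
    const arma::uword ka = std::min<arma::uword>(na - 1, t);
    for (arma::uword i = 0; i < m; ++i) y[i] = b[0] * X.colptr(t)[i];
    for (arma::uword k = 1; k <= kb; ++k) {
      const double bk = b[k];
      const double* xk = X.colptr(t - k);
      for (arma::uword i = 0; i < m; ++i) y[i] += bk * xk[i];
    }
    for (arma::uword k = 1; k <= ka; ++k) {
      const double ak = a[k];
      const double* yk = Y.colptr(t - k);
      for (arma::uword i = 0; i < m; ++i) y[i] -= ak * yk[i];
    }
    if (a0 != 1.0) for (arma::uword i = 0; i < m; ++i) y[i] /= a0;
  }
  X = Y;
}

// Zero-phase forward-backward IIR filtering of every row of X.
// Zero padding at the tail before each pass (the classic
// filter-reverse-filter-reverse scheme); callers exclude edge samples
// where transients matter.
// [[Rcpp::export]]
arma::mat filtfilt_rows_cpp(const arma::vec& b, const arma::vec& a,
                            const arma::mat& X) {
  const arma::uword npad = 2 * std::max(a.n_elem, b.n_elem);
  const arma::uword n = X.n_cols;
  arma::mat W(X.n_rows, n + npad, arma::fill::zeros);
  W.head_cols(n) = X;
  iir_cols(b, a, W);
  W = arma::fliplr(W);
  iir_cols(b, a, W);
  W = arma::fliplr(W);
  return W.head_cols(n);
}
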