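#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// AR recursion x_t = sum_r A_r x_{t-r} + e_t, run over the innovation matrix
// (channels x total samples); the first burn_in columns are discarded.
// [[Rcpp::export]]
arma::mat mvar_recursion_cpp(const arma::cube& coeffs, const arma::mat& innov,
                             int burn_in) {
  const arma::uword n = coeffs.n_rows;
  const arma::uword p = coeffs.n_slices;
  const arma::uword total = innov.n_cols;
  arma::mat x(n, total, arma::fill::zeros);
  for (arma::uword t = 0; t < total; ++t) {
    arma::vec acc = innov.col(t);
    for (arma::uword r = 1; r <= p && r <= t; ++r)
      acc += coeffs.slice(r - 1) * x.col(t - r);
    x.col(t) = acc;
  }
  return x.cols(burn_in, total - 1);
}
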