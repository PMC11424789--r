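#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Nuttall-Strand multichannel lattice recursion. Input x is channels x
// samples, already de-meaned. Returns the forward coefficient cube
// A_1..A_p and the final forward prediction-error covariance.
// Stage covariances divide by the number of lagged sample pairs
// (unbiased normalisation). Prediction-error sequences are double-
// buffered and accessed through aliasing views to avoid per-stage
// copies.
// [[Rcpp::export]]
Rcpp::List ns_lattice_cpp(const arma::mat& x, int order) {
  const arma::uword M = x.n_rows;
  const arma::uword N = x.n_cols;
  arma::mat Fa = x, Ba = x, Fb(M, N), Bb(M, N);
  arma::mat *Fc = &Fa, *Bc_ = &Ba, *Fn = &Fb, *Bn = &Bb;
  arma::mat PF = x * x.t() / double(N - 1);
  arma::mat PB = PF;
  if (arma::rcond(PF) < 1e-12)
    Rcpp::stop("numerically singular prediction-error covariance; check for rank-deficient (duplicated or constant) channels");
  arma::cube A(M, M, order, arma::fill::zeros);
  arma::cube Bcoef(M, M, order, arma::fill::zeros);
  arma::uword len = N;   // columns in the current error sequences
  for (int m = 1; m <= order; ++m) {
    const arma::uword nterm = len - 1;
    // aliasing views: forward errors at t = (m..), backward at t-1
    const arma::mat Fm(Fc->colptr(1), M, nterm, false, true);
    const arma::mat Bm(Bc_->colptr(0), M, nterm, false, true);
    arma::mat Pfh = Fm * Fm.t() / double(nterm);
    arma::mat Pbh = Bm * Bm.t() / double(nterm);
    arma::mat Dh = Fm * Bm.t() / double(nterm);
    arma::mat iPF = arma::inv(PF);
    arma::mat iPB = arma::inv(PB);
    arma::mat D;
    if (!arma::syl(D, Pfh * iPF, iPB * Pbh, -2.0 * Dh))
      Rcpp::stop("Sylvester solve failed in Nuttall-Strand stage %d", m);
    arma::mat KF = D * iPB;
    arma::mat KB = D.t() * iPF;
    // Whittle coefficient update (every new slice needs previous-stage
    // values of both coefficient sets, so snapshot them first)
    if (m > 1) {
      arma::cube Aold = A.slices(0, m - 2);
      arma::cube Bold = Bcoef.slices(0, m - 2);
      for (int i = 1; i < m; ++i) {
        A.slice(i - 1) = Aold.slice(i - 1) - KF * Bold.slice(m - i - 1);
        Bcoef.slice(i - 1) = Bold.slice(i - 1) - KB * Aold.slice(m - i - 1);
      }
    }
    A.slice(m - 1) = KF;
    Bcoef.slice(m - 1) = KB;
    // residual update into the spare buffers
    arma::mat Fnv(Fn->colptr(0), M, nterm, false, true);
    arma::mat Bnv(Bn->colptr(0), M, nterm, false, true);
    Fnv = Fm - KF * Bm;
    Bnv = Bm - KB * Fm;
    std::swap(Fc, Fn);
    std::swap(Bc_, Bn);
    len = nterm;
    PF -= D * iPB * D.t();
    PB -= D.t() * iPF * D;
    PF = arma::symmatu(PF);
    PB = arma::symmatu(PB);
    if (arma::rcond(PF) < 1e-12)
      Rcpp::stop("prediction-error covariance became numerically singular at stage %d; channels may be rank deficient", m);
  }
  return Rcpp::List::create(Rcpp::Named("coeffs") = A,
                            Rcpp::Named("noise_cov") = PF);
}
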