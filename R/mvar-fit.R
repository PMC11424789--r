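#' Fit an MVAR model by the Nuttall-Strand lattice algorithm
#'
#' Multichannel Burg-type recursion: at each stage forward and backward
#' prediction errors are combined into a partial cross-correlation matrix
#' \eqn{\Delta} obtained from the Sylvester equation
#' \deqn{\hat P_f P_f^{-1} \Delta + \Delta P_b^{-1} \hat P_b = 2 \hat\Delta,}
#' which jointly minimises the normalised forward and backward
#' prediction-error power (\eqn{\hat P_f, \hat P_b, \hat\Delta} are the
#' stage's empirical error moments; \eqn{P_f, P_b} the recursion error
#' covariances). Reflection matrices \eqn{K_f = \Delta P_b^{-1}},
#' \eqn{K_b = \Delta^\top P_f^{-1}}, the coefficient matrices (Whittle
#' update) and the error covariances are propagated up to the requested
#' order. All stage covariances use unbiased normalisation: sums are
#' divided by the number of lagged sample pairs available at that stage,
#' not by the total sample count.
#'
#' @param x numeric matrix `n_channels x n_samples`; de-meaned internally.
#' @param order model order `p` (number of lags), default 40.
#' @return an [mvar_model()] whose `coeffs` are the forward coefficient
#'   matrices `A_1..A_p` and whose `noise_cov` is the final forward
#'   prediction-error (innovation) covariance.
#' @examples
#' m <- mvar_model(array(c(0.5, 0.3, 0, 0.4), c(2, 2, 1)))
#' x <- simulate_mvar(m, 5000, seed = 1)
#' fit <- fit_mvar_nuttall_strand(x, order = 1)
#' @export
fit_mvar_nuttall_strand <- function(x, order = 40L) {
  stopifnot(is.matrix(x), order >= 1)
  N <- ncol(x)
  if (N <= 3 * order)
    stop(sprintf("need more than %d samples for order %d (got %d)",
                 3 * order, order, N))
  res <- ns_lattice_cpp(x - rowMeans(x), as.integer(order))
  mvar_model(res$coeffs, (res$noise_cov + t(res$noise_cov)) / 2)
}
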