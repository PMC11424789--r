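#' Multivariate autoregressive (MVAR) model container
#'
#' An MVAR(p) model describes each channel as a lagged linear combination of
#' all channels plus Gaussian innovation noise:
#' \deqn{x_t = \sum_{r=1}^{p} A_r x_{t-r} + e_t, \quad e_t \sim N(0, \Sigma).}
#' The same container holds both ground-truth models used by the synthetic
#' cohort generator and models estimated from data.
#'
#' @param coeffs numeric array `n_channels x n_channels x order`; slice `r`
#'   holds the lag-`r` coefficient matrix `A_r` (entry `[i, j]` couples source
#'   channel `j` into target channel `i`).
#' @param noise_cov symmetric positive-definite innovation covariance
#'   (`n_channels x n_channels`). Defaults to the identity.
#' @param check if `TRUE`, validate symmetry/positive-definiteness and
#'   finiteness. Stationarity is *not* enforced here; use
#'   [is_stationary()] / [spectral_radius()].
#' @return an object of class `mvar_model` with elements `coeffs`,
#'   `noise_cov`, `order`, `n_channels`.
#' @seealso [simulate_mvar()], [fit_mvar_nuttall_strand()], [pdc_spectrum()]
#' @export
mvar_model <- function(coeffs, noise_cov = NULL, check = TRUE) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(nrow(coeffs), ncol(coeffs), 1L))
  stopifnot(is.array(coeffs), length(dim(coeffs)) == 3L,
            dim(coeffs)[1] == dim(coeffs)[2])
  n <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  if (is.null(noise_cov)) noise_cov <- diag(n)
  if (check) {
    if (!all(is.finite(coeffs))) stop("MVAR coefficients must be finite")
    if (!isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-8)))
      stop("noise_cov must be symmetric")
    ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("noise_cov must be positive definite")
  }
  structure(list(coeffs = coeffs, noise_cov = noise_cov,
                 order = p, n_channels = n),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR model: %d channels, order %d, companion spectral radius %.4f\n",
              x$n_channels, x$order, spectral_radius(x)))
  invisible(x)
}

#' Companion matrix of an MVAR model
#'
#' Stacks the lag coefficient matrices into the `(p*n) x (p*n)` block
#' companion form whose eigenvalue moduli decide stationarity.
#'
#' @param model an [mvar_model()].
#' @return a `(order*n_channels)` square matrix.
#' @export
companion_matrix <- function(model) {
  n <- model$n_channels
  p <- model$order
  C <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) C[1:n, ((r - 1) * n + 1):(r * n)] <- model$coeffs[, , r]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  C
}

#' Companion spectral radius
#'
#' @param model an [mvar_model()].
#' @return largest eigenvalue modulus of the companion matrix; the model is
#'   stationary iff this is `< 1`.
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' Is an MVAR model stationary?
#'
#' @param model an [mvar_model()].
#' @param margin stationarity bound on the companion spectral radius.
#' @return logical.
#' @export
is_stationary <- function(model, margin = 1) {
  spectral_radius(model) < margin
}

#' Simulate an MVAR process
#'
#' Runs the AR recursion with Gaussian innovations drawn from the model's
#' innovation covariance; a burn-in prefix is discarded so the returned
#' samples come from the stationary distribution. The same seed always
#' yields the same output.
#'
#' @param model a stationary [mvar_model()].
#' @param n_samples number of samples to return.
#' @param burn_in samples discarded at the start (default 500).
#' @param seed integer RNG seed.
#' @return `n_channels x n_samples` numeric matrix.
#' @export
simulate_mvar <- function(model, n_samples, burn_in = 500L, seed = 1L) {
  stopifnot(n_samples > 0)
  if (!is_stationary(model))
    stop("simulate_mvar: model is not stationary (companion spectral radius >= 1)")
  n <- model$n_channels
  total <- n_samples + burn_in
  L <- t(chol(model$noise_cov))
  innov <- withr::with_seed(seed,
    L %*% matrix(stats::rnorm(n * total), n, total))
  mvar_recursion_cpp(model$coeffs, innov, as.integer(burn_in))
}
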