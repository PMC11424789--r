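#' Standard EEG frequency bands
#'
#' Closed frequency intervals (Hz) for the four analysis bands:
#' delta 1.0-4.0, theta 5.0-8.0, alpha 9.0-12.0, beta 13-30.
#' Grid frequencies falling between band edges (e.g. 4.5 Hz) belong to no
#' band and are ignored by [band_average()].
#'
#' @return named list of length-2 numeric vectors (band edges, Hz).
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(5, 8), alpha = c(9, 12), beta = c(13, 30))
}

#' Default PDC frequency grid
#'
#' @param fmin,fmax,by grid limits and spacing in Hz (default 0.5 to 45 by
#'   0.5).
#' @return increasing numeric vector of frequencies.
#' @export
pdc_freq_grid <- function(fmin = 0.5, fmax = 45, by = 0.5) {
  seq(fmin, fmax, by = by)
}

#' Partial directed coherence spectrum of an MVAR model
#'
#' Evaluates \eqn{\bar A(f) = I - \sum_{r=1}^p A_r e^{-i 2\pi f r / f_s}}
#' on the frequency grid and the column-normalised PDC
#' \deqn{\pi_{ij}(f) = |\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2},}
#' quantifying directed influence from source channel `j` to target `i`.
#' By construction \eqn{\sum_i \pi_{ij}(f)^2 = 1} for every source column
#' at every frequency.
#'
#' @param model an [mvar_model()].
#' @param freq_grid_hz increasing frequencies, all below `fs_hz/2`.
#' @param fs_hz sampling rate of the data the model describes.
#' @param variant `"pdc"` (original column-normalised magnitude, default),
#'   `"gpdc"` (generalised PDC, columns weighted by inverse innovation
#'   standard deviations) or `"sq"` (squared PDC).
#' @return object of class `pdc_spectrum`: list with `values`
#'   (`n_freqs x n x n` array, target x source in the last two margins),
#'   `freq_grid_hz` and `fs_hz`.
#' @export
pdc_spectrum <- function(model, freq_grid_hz = pdc_freq_grid(), fs_hz,
                         variant = c("pdc", "gpdc", "sq")) {
  variant <- match.arg(variant)
  stopifnot(all(freq_grid_hz < fs_hz / 2), all(diff(freq_grid_hz) > 0))
  n <- model$n_channels
  p <- model$order
  nf <- length(freq_grid_hz)
  # stack A_r as (n*n) x p and multiply by the p x nf complex exponentials
  Astack <- matrix(model$coeffs, n * n, p)
  E <- exp(-1i * 2 * pi * outer(seq_len(p), freq_grid_hz) / fs_hz)
  Af <- -Astack %*% E                       # (n*n) x nf
  Af <- Af + as.vector(diag(n))             # add I to every frequency slice
  w <- if (variant == "gpdc") 1 / sqrt(diag(model$noise_cov)) else rep(1, n)
  Am <- Mod(Af) * w                        # (n*n) x nf, target index fastest
  src <- rep(seq_len(n), each = n)         # source (column) index per row
  cn2 <- rowsum(Am^2, src)                 # n x nf column sums of squares
  if (any(cn2 == 0)) stop("zero column norm in A(f); model appears degenerate")
  pij <- Am / sqrt(cn2)[src, , drop = FALSE]
  if (variant == "sq") pij <- pij^2
  vals <- aperm(array(pij, c(n, n, nf)), c(3, 1, 2))
  structure(list(values = vals, freq_grid_hz = freq_grid_hz, fs_hz = fs_hz,
                 variant = variant),
            class = "pdc_spectrum")
}

#' Band-averaged connectivity matrices
#'
#' Averages |PDC| over the grid frequencies inside each closed band
#' interval, then over epochs (one spectrum per epoch).
#'
#' @param pdc_per_epoch a single `pdc_spectrum` or a list of them with
#'   identical frequency grids.
#' @param bands named list of band edges, as from [eeg_bands()].
#' @return object of class `band_connectivity`: named list of
#'   `n x n` matrices (target x source), entries in `[0, 1]`.
#' @export
band_average <- function(pdc_per_epoch, bands = eeg_bands()) {
  if (inherits(pdc_per_epoch, "pdc_spectrum")) pdc_per_epoch <- list(pdc_per_epoch)
  stopifnot(length(pdc_per_epoch) >= 1)
  grid <- pdc_per_epoch[[1]]$freq_grid_hz
  for (s in pdc_per_epoch)
    if (!isTRUE(all.equal(s$freq_grid_hz, grid)))
      stop("all epoch spectra must share the same frequency grid")
  out <- lapply(bands, function(b) {
    sel <- which(grid >= b[1] & grid <= b[2])
    if (length(sel) == 0)
      stop(sprintf("band [%g, %g] Hz contains no grid frequency", b[1], b[2]))
    mats <- lapply(pdc_per_epoch, function(s) {
      colMeans(s$values[sel, , , drop = FALSE], dims = 1)
    })
    Reduce(`+`, mats) / length(mats)
  })
  structure(out, class = "band_connectivity")
}

#' Region-wise inflow and outflow per band
#'
#' For a band connectivity matrix `conn` (target x source),
#' `inflow[i] = mean over j != i of conn[i, j]` and
#' `outflow[j] = mean over i != j of conn[i, j]`; both lie in `[0, 1]` and
#' the two vectors share the same mean (the off-diagonal mean).
#'
#' @param band_conn a [band_average()] result (or a named list of square
#'   matrices).
#' @return list with matrices `inflow` and `outflow`
#'   (`n_regions x n_bands`).
#' @export
inflow_outflow <- function(band_conn) {
  stopifnot(length(band_conn) >= 1)
  n <- nrow(band_conn[[1]])
  if (n < 2) stop("inflow/outflow need at least 2 regions")
  inflow <- sapply(band_conn, function(m) {
    stopifnot(nrow(m) == ncol(m))
    (rowSums(m) - diag(m)) / (n - 1)
  })
  outflow <- sapply(band_conn, function(m) (colSums(m) - diag(m)) / (n - 1))
  list(inflow = as.matrix(inflow), outflow = as.matrix(outflow))
}
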