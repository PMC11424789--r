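#' Weighted minimum-norm inverse operator
#'
#' Computes the depth-weighted minimum-norm kernel
#' \deqn{K = R G^\top (G R G^\top + \lambda^2 C)^{-1}}
#' where `G` is the lead-field gain, `C` the sensor noise covariance and
#' `R` the diagonal source weighting with
#' \eqn{R_{ii} = \lVert g_i \rVert^{-2\gamma}} (depth weighting; `gamma = 0`
#' disables it).
#'
#' @param leadfield a [lead_field()] (or any list with a `gain` matrix).
#' @param noise_cov sensor noise covariance; identity by default.
#' @param lambda_reg regularisation parameter \eqn{\lambda}; if `NULL`,
#'   chosen from an assumed power signal-to-noise ratio of 3:
#'   \eqn{\lambda^2 = \mathrm{tr}(G R G^\top) / (9\,\mathrm{tr}(C))}.
#' @param depth_gamma depth-weighting exponent (default 0.5).
#' @return an `inverse_operator` list with `kernel`
#'   (`n_sources x n_sensors`), `lambda_reg` and `depth_gamma`.
#' @export
compute_wmne_operator <- function(leadfield, noise_cov = NULL,
                                  lambda_reg = NULL, depth_gamma = 0.5) {
  G <- leadfield$gain
  if (any(colSums(G^2) == 0)) stop("lead field has all-zero columns")
  ns <- nrow(G)
  if (is.null(noise_cov)) noise_cov <- diag(ns)
  rdiag <- colSums(G^2)^(-depth_gamma)
  GR <- sweep(G, 2, rdiag, `*`)          # G R
  gram <- GR %*% t(G)                    # G R G'
  if (is.null(lambda_reg))
    lambda_reg <- sqrt(sum(diag(gram)) / (9 * sum(diag(noise_cov))))
  M <- gram + lambda_reg^2 * noise_cov
  if (rcond(M) < 1e-14)
    stop("regularized Gram matrix is numerically singular; increase lambda_reg or check the lead field rank")
  kernel <- t(GR) %*% solve(M)
  structure(list(kernel = kernel, lambda_reg = lambda_reg,
                 depth_gamma = depth_gamma),
            class = "inverse_operator")
}

#' Apply an inverse operator to sensor epochs
#'
#' Per-epoch matrix product (no temporal mixing across samples).
#'
#' @param epoch_set an [epoch_set()] of sensor data.
#' @param operator an [compute_wmne_operator()] result.
#' @return array `n_epochs x n_sources x n_samples` of source time
#'   courses, with the epoch set's `fs_hz` attached as attribute.
#' @export
apply_inverse <- function(epoch_set, operator) {
  d <- dim(epoch_set$epochs)
  if (ncol(operator$kernel) != d[2])
    stop(sprintf("operator expects %d sensors but epochs have %d channels",
                 ncol(operator$kernel), d[2]))
  ns <- nrow(operator$kernel)
  out <- array(0, c(d[1], ns, d[3]))
  for (e in seq_len(d[1]))
    out[e, , ] <- operator$kernel %*% epoch_set$epochs[e, , ]
  attr(out, "fs_hz") <- epoch_set$fs_hz
  out
}

#' Aggregate source epochs into region time courses
#'
#' For each macro region, computes a representative time course as the
#' per-sample mean of its sources after sign alignment: each source is
#' flipped so its correlation with the region's first principal temporal
#' component (computed over all epochs jointly) is nonnegative. Signed
#' averaging with sign alignment preserves zero-mean oscillatory structure
#' and phase, which the downstream MVAR/PDC estimation requires;
#' averaging magnitudes would rectify the signal.
#'
#' @param source_epochs array `n_epochs x n_sources x n_samples`
#'   (from [apply_inverse()]).
#' @param source_region_map integer vector mapping each source to a region
#'   index `1..n_regions`.
#' @param n_regions number of regions (default `max(source_region_map)`).
#' @param region_labels optional labels, defaults to
#'   [macro_region_labels()] when `n_regions == 12`.
#' @return a `region_epochs` list: `epochs`
#'   (`n_epochs x n_regions x n_samples`), `fs_hz`, `region_labels`.
#' @export
aggregate_regions <- function(source_epochs, source_region_map,
                              n_regions = max(source_region_map),
                              region_labels = NULL) {
  d <- dim(source_epochs)
  stopifnot(length(source_region_map) == d[2])
  missing_regions <- setdiff(seq_len(n_regions), unique(source_region_map))
  if (length(missing_regions) > 0)
    stop(sprintf("region(s) with no sources: %s",
                 paste(missing_regions, collapse = ", ")))
  if (is.null(region_labels))
    region_labels <- if (n_regions == 12) macro_region_labels()
                     else sprintf("region%02d", seq_len(n_regions))
  out <- array(0, c(d[1], n_regions, d[3]))
  for (r in seq_len(n_regions)) {
    idx <- which(source_region_map == r)
    # n_sources_in_region x (epochs*samples), epochs concatenated in time
    flat <- matrix(aperm(source_epochs[, idx, , drop = FALSE], c(2, 3, 1)),
                   nrow = length(idx))
    if (length(idx) == 1) {
      signs <- 1
    } else {
      # sign of each source's correlation with the first principal
      # temporal component equals the sign of its loading on the first
      # eigenvector of the source covariance
      cc <- eigen(tcrossprod(flat - rowMeans(flat)),
                  symmetric = TRUE)$vectors[, 1]
      signs <- ifelse(cc >= 0, 1, -1)
      # the principal component's own sign is arbitrary: orient so that a
      # majority of sources keep their sign (first source wins a tie)
      if (sum(signs < 0) > sum(signs > 0) ||
          (sum(signs < 0) == sum(signs > 0) && signs[1] < 0))
        signs <- -signs
    }
    for (e in seq_len(d[1])) {
      m <- matrix(source_epochs[e, idx, , drop = FALSE], length(idx), d[3])
      out[e, r, ] <- colMeans(m * signs)
    }
  }
  structure(list(epochs = out,
                 fs_hz = attr(source_epochs, "fs_hz"),
                 region_labels = region_labels),
            class = "region_epochs")
}

#' The 12 macro region labels
#'
#' @return character vector: frontal, temporomedial, temporolateral,
#'   parietal, occipital and thalamus, right/left.
#' @export
macro_region_labels <- function() {
  c("frontal_R", "frontal_L", "temporomedial_R", "temporomedial_L",
    "temporolateral_R", "temporolateral_L", "parietal_R", "parietal_L",
    "occipital_R", "occipital_L", "thalamus_R", "thalamus_L")
}

#' Load the packaged fine-to-macro parcellation map
#'
#' Reads a two-column mapping from 104 fine anatomical parcels to the 12
#' macro regions used throughout the pipeline. Users may substitute their
#' own table with the same columns (`fine_region`, `macro_region`).
#'
#' @param path path to a TSV with columns `fine_region`, `macro_region`;
#'   defaults to the table shipped with the package.
#' @return a data.frame with the two columns; the macro labels are exactly
#'   [macro_region_labels()].
#' @export
load_parcellation <- function(path = system.file("extdata",
                                                 "aal_macro_map.tsv",
                                                 package = "restflow")) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fine_region", "macro_region") %in% names(map)))
  if (anyDuplicated(map$fine_region))
    stop("parcellation maps a fine region twice")
  extra <- setdiff(unique(map$macro_region), macro_region_labels())
  if (length(extra) > 0)
    stop(sprintf("unknown macro region label(s): %s",
                 paste(extra, collapse = ", ")))
  map
}

#' Decimate region epochs with anti-alias filtering
#'
#' Low-pass filters (zero-phase 8th-order Butterworth at 80% of the target
#' Nyquist) and subsamples each region time course by an integer factor.
#' Used by the default pipeline to bring 1000 Hz data to 250 Hz before
#' MVAR fitting, so that a model of order 40 spans 160 ms of signal
#' history rather than 40 ms.
#'
#' @param region_epochs a `region_epochs` (or [epoch_set()]-like) object.
#' @param factor integer decimation factor.
#' @return the decimated object with updated `fs_hz`.
#' @export
decimate_epochs <- function(region_epochs, factor) {
  factor <- as.integer(factor)
  if (factor <= 1) return(region_epochs)
  d <- dim(region_epochs$epochs)
  fs <- region_epochs$fs_hz
  bf <- signal::butter(4, 0.8 / factor, type = "low")
  keep <- seq(1, d[3], by = factor)
  out <- array(0, c(d[1], d[2], length(keep)))
  for (e in seq_len(d[1])) {
    v <- filtfilt_rows_cpp(bf$b, bf$a,
                           matrix(region_epochs$epochs[e, , ], d[2], d[3]))
    out[e, , ] <- v[, keep]
  }
  res <- region_epochs
  res$epochs <- out
  res$fs_hz <- fs / factor
  res
}
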