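#' Sensor-level recording container
#'
#' @param data numeric matrix `n_channels x n_samples` (microvolts).
#' @param fs_hz sampling rate (> 0).
#' @param channel_labels unique channel labels; defaults to `"E001"`, ...
#' @param bad_channels subset of `channel_labels` flagged as bad.
#' @param artifact_refs optional matrix of reference artifact waveforms
#'   (rows, e.g. EOG/ECG-like) with the same sample count as `data`.
#' @return a `sensor_recording` list.
#' @export
sensor_recording <- function(data, fs_hz, channel_labels = NULL,
                             bad_channels = character(),
                             artifact_refs = NULL) {
  stopifnot(is.matrix(data))
  if (is.null(channel_labels))
    channel_labels <- sprintf("E%03d", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel required")
  if (!all(bad_channels %in% channel_labels))
    stop("bad_channels must be a subset of channel_labels")
  if (!is.null(artifact_refs) && ncol(artifact_refs) != ncol(data))
    stop("artifact_refs must have the same number of samples as data")
  structure(list(data = data, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 bad_channels = bad_channels,
                 artifact_refs = artifact_refs),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("Sensor recording: %d channels x %d samples @ %g Hz (%d bad)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, length(x$bad_channels)))
  invisible(x)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (`signal::filtfilt`), giving an effective 8th-order zero-phase filter.
#' Removes DC and slow drifts while preserving passband amplitude and
#' phase; phase preservation matters because directed connectivity is
#' estimated downstream.
#'
#' @param recording a [sensor_recording()].
#' @param cutoff_hz high-pass cutoff (default 0.5 Hz); must be below
#'   Nyquist.
#' @return a filtered copy of the recording (artifact references are
#'   filtered alongside the data so later correlations stay meaningful).
#' @export
highpass_filter <- function(recording, cutoff_hz = 0.5) {
  fs <- recording$fs_hz
  if (cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, fs / 2))
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "high")
  out <- recording
  out$data <- filtfilt_rows_cpp(bf$b, bf$a, recording$data)
  if (!is.null(recording$artifact_refs))
    out$artifact_refs <- filtfilt_rows_cpp(bf$b, bf$a,
                                           recording$artifact_refs)
  out
}

#' Detect bad channels by robust variance and flatline criteria
#'
#' Flags channels whose log-variance is a robust outlier (|z| beyond
#' `z_thresh` using median/MAD) or which are essentially flat
#' (near-constant signal).
#'
#' @param recording a [sensor_recording()] with at least 4 channels.
#' @param z_thresh robust z-score threshold (default 4).
#' @return character vector of flagged channel labels.
#' @export
detect_bad_channels <- function(recording, z_thresh = 4) {
  x <- recording$data
  if (nrow(x) < 4) stop("need at least 4 channels for outlier detection")
  v <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  flat <- v < 1e-12 * max(v, 1e-300)
  lv <- log(pmax(v, 1e-300))
  usable <- !flat
  med <- stats::median(lv[usable])
  s <- stats::mad(lv[usable])
  z <- if (s > 0) (lv - med) / s else rep(0, length(lv))
  flagged <- flat | (usable & abs(z) > z_thresh)
  recording$channel_labels[flagged]
}

#' Remove artifact components by seeded ICA
#'
#' Drops bad channels, decomposes the remaining channels into maximally
#' statistically independent components (symmetric FastICA with a tanh
#' contrast on a whitened, dimension-reduced representation of at most
#' `n_comp` components), and subtracts every component whose absolute
#' temporal correlation with any reference waveform in
#' `recording$artifact_refs` exceeds `corr_thresh`. Channel and sample
#' counts are never altered; channels flagged bad pass through untouched.
#'
#' @param recording a [sensor_recording()] with `artifact_refs` present
#'   and at least 8 good channels.
#' @param corr_thresh absolute correlation threshold (default 0.7).
#' @param seed integer seed for the ICA initialisation (reproducible).
#' @param n_comp maximum number of components (default
#'   `min(n_good_channels, 20)`).
#' @return a cleaned copy of the recording.
#' @export
remove_artifact_components <- function(recording, corr_thresh = 0.7,
                                       seed = 1L, n_comp = NULL) {
  if (is.null(recording$artifact_refs))
    stop("recording has no artifact reference signals")
  good <- !(recording$channel_labels %in% recording$bad_channels)
  if (sum(good) < 8) stop("need at least 8 good channels for ICA")
  X <- recording$data[good, , drop = FALSE]
  k <- if (is.null(n_comp)) min(sum(good), 20L) else n_comp
  dec <- fast_ica(X, n_comp = k, seed = seed)
  refs <- recording$artifact_refs
  cors <- abs(stats::cor(t(dec$S), t(refs)))
  remove <- which(apply(cors, 1, max) > corr_thresh)
  out <- recording
  if (length(remove) > 0) {
    contrib <- dec$A[, remove, drop = FALSE] %*% dec$S[remove, , drop = FALSE]
    out$data[good, ] <- X - contrib
  }
  out
}

# Deflationary FastICA with tanh contrast on PCA-whitened data.
# Components are extracted one at a time with Gram-Schmidt decorrelation;
# extraction stops at the first component whose fixed-point iteration does
# not converge. This matches the statistics of EEG: only the non-Gaussian
# directions (artifacts, transients) are identifiable, while the
# near-Gaussian background subspace admits no unique rotation — stopping
# there leaves it untouched, which is exactly what artifact removal
# requires. Failing on the very first component is a genuine
# decomposition failure and raises an error.
# Returns unmixed sources S (n_extracted x n_samples) and the mixing
# matrix A mapping sources back to (centered) channels: Xc ~ A %*% S.
fast_ica <- function(X, n_comp, seed = 1L, max_iter = 200L, tol = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  N <- ncol(Xc)
  C <- tcrossprod(Xc) / (N - 1)
  e <- eigen(C, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-10)
  keep <- pos[seq_len(min(n_comp, length(pos)))]
  K <- t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep])
  Z <- K %*% Xc
  k <- nrow(Z)
  Winit <- withr::with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- matrix(0, 0, k)
  for (comp in seq_len(k)) {
    w <- Winit[comp, ]
    if (nrow(W) > 0) w <- w - as.vector(crossprod(W, W %*% w))
    w <- w / sqrt(sum(w^2))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- as.vector(w %*% Z)
      g <- tanh(wz)
      w1 <- as.vector(Z %*% g) / N - mean(1 - g^2) * w
      if (nrow(W) > 0) w1 <- w1 - as.vector(crossprod(W, W %*% w1))
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) break
      w1 <- w1 / nrm
      d <- abs(1 - abs(sum(w1 * w)))
      w <- w1
      if (d < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      if (comp == 1)
        stop(sprintf("FastICA failed to extract any component within %d iterations; the data may have no identifiable non-Gaussian structure", max_iter))
      break
    }
    W <- rbind(W, w)
  }
  S <- W %*% Z
  A <- MASS_ginv(K) %*% t(W)
  list(S = S, A = A, W = W, K = K, n_extracted = nrow(W))
}

# Moore-Penrose pseudoinverse via SVD (whitening matrices are short and fat)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Epoch container
#'
#' @param epochs numeric array `n_epochs x n_channels x n_samples`.
#' @param fs_hz sampling rate.
#' @param epoch_len_s epoch length in seconds; `fs_hz * epoch_len_s` must
#'   equal the sample dimension exactly.
#' @param channel_labels optional labels.
#' @return an `epoch_set` list.
#' @export
epoch_set <- function(epochs, fs_hz, epoch_len_s, channel_labels = NULL) {
  stopifnot(length(dim(epochs)) == 3)
  if (round(fs_hz * epoch_len_s) != dim(epochs)[3])
    stop("sample count must equal fs_hz * epoch_len_s exactly")
  structure(list(epochs = epochs, fs_hz = fs_hz, epoch_len_s = epoch_len_s,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' Extract clean, non-overlapping epochs
#'
#' Selects the earliest `n_epochs` disjoint windows of `epoch_len_s`
#' seconds whose samples are all marked clean, scanning left to right
#' (deterministic tie-breaking by start index). Bad channels are dropped.
#'
#' @param recording a [sensor_recording()].
#' @param n_epochs number of epochs (default 10).
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param clean_mask logical vector (length `n_samples`), `TRUE` where the
#'   sample is artifact-free. Defaults to the recording's
#'   `artifact_mask` attribute negated, or all-clean if absent.
#' @return an [epoch_set()] (`n_epochs x n_good_channels x samples`).
#' @export
extract_epochs <- function(recording, n_epochs = 10L, epoch_len_s = 5,
                           clean_mask = NULL) {
  fs <- recording$fs_hz
  len <- round(epoch_len_s * fs)
  n <- ncol(recording$data)
  if (is.null(clean_mask)) {
    am <- attr(recording, "artifact_mask")
    clean_mask <- if (is.null(am)) rep(TRUE, n) else !am
  }
  stopifnot(length(clean_mask) == n)
  starts <- integer(0)
  # scan runs of clean samples and tile epochs into each run
  r <- rle(clean_mask)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    navail <- r$lengths[k] %/% len
    if (navail == 0) next
    s <- begs[k] + (seq_len(navail) - 1L) * len
    starts <- c(starts, s)
    if (length(starts) >= n_epochs) break
  }
  if (length(starts) < n_epochs)
    stop(sprintf("insufficient clean data: found %d clean epoch(s) of %g s, need %d",
                 length(starts), epoch_len_s, n_epochs))
  starts <- starts[seq_len(n_epochs)]
  good <- !(recording$channel_labels %in% recording$bad_channels)
  ep <- array(0, c(n_epochs, sum(good), len))
  for (e in seq_len(n_epochs))
    ep[e, , ] <- recording$data[good, starts[e]:(starts[e] + len - 1L)]
  out <- epoch_set(ep, fs, epoch_len_s,
                   channel_labels = recording$channel_labels[good])
  attr(out, "starts") <- starts
  out
}
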