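# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings with a common sampling rate. Covers exactly the
# subset of the format this package emits: 16-bit samples, one common
# physical range per channel, 1 s data records. (No installed R package
# provides EDF I/O, so the format is handled here directly.)

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# 8-char ASCII numeric field: most precise decimal that fits the slot
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- as.character(signif(x, d))
    if (nchar(s) <= 8) return(edf_pad(s, 8))
  }
  edf_pad(formatC(x, format = "e", digits = 1), 8)
}

#' Write a recording to an EDF file
#'
#' Stores `n_channels x n_samples` data as 16-bit EDF with 1 s data
#' records. Each channel is scaled to its own symmetric physical range;
#' the quantization step is `(2 * max|x|) / 65534` per channel. The
#' sample count is padded with zeros up to a whole number of records.
#'
#' @param recording a [sensor_recording()]; `fs_hz` must be a positive
#'   integer.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording$data
  fs <- recording$fs_hz
  if (abs(fs - round(fs)) > 1e-9 || fs <= 0)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(x)
  nrec <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < nrec * fs)
    x <- cbind(x, matrix(0, nch, nrec * fs - ncol(x)))
  pmaxs <- pmax(apply(abs(x), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("synthetic patient", 80))
  wr(edf_pad("restflow recording", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(edf_pad(256 * (1 + nch), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(nrec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(nch, 4))
  labs <- recording$channel_labels
  for (l in labs) wr(edf_pad(l, 16))
  for (i in seq_len(nch)) wr(edf_pad("", 80))
  for (i in seq_len(nch)) wr(edf_pad("uV", 8))
  for (i in seq_len(nch)) wr(edf_num8(-pmaxs[i]))
  for (i in seq_len(nch)) wr(edf_num8(pmaxs[i]))
  for (i in seq_len(nch)) wr(edf_pad("-32767", 8))
  for (i in seq_len(nch)) wr(edf_pad("32767", 8))
  for (i in seq_len(nch)) wr(edf_pad("", 80))
  for (i in seq_len(nch)) wr(edf_pad(fs, 8))
  for (i in seq_len(nch)) wr(edf_pad("", 32))
  # physical ranges as re-parsed from their 8-char ASCII form, so the
  # scaling used here matches what any reader will recover
  pm <- vapply(pmaxs, function(p) as.numeric(edf_num8(p)), 0)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch)) {
      dig <- as.integer(round(x[i, idx] / pm[i] * 32767))
      dig <- pmin(pmax(dig, -32767L), 32767L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports continuous EDF recordings in which every signal shares the
#' same sampling rate.
#'
#' @param path EDF file path.
#' @return a [sensor_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdn <- function(n) {
    v <- suppressWarnings(as.numeric(trimws(rd(n))))
    if (is.na(v)) stop("malformed EDF header: non-numeric field")
    v
  }
  version <- trimws(rd(8))
  if (version != "0") stop("malformed EDF header: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  rdn(8)                      # header length
  rd(44)
  nrec <- rdn(8)
  dur <- rdn(8)
  nch <- as.integer(rdn(4))
  labs <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- vapply(seq_len(nch), function(i) rdn(8), 0)
  pmax_ <- vapply(seq_len(nch), function(i) rdn(8), 0)
  dmin_ <- vapply(seq_len(nch), function(i) rdn(8), 0)
  dmax_ <- vapply(seq_len(nch), function(i) rdn(8), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) rdn(8), 0)
  if (length(unique(spr)) != 1)
    stop("read_edf supports only a common sampling rate across signals")
  for (i in seq_len(nch)) rd(32)
  fs <- spr[1] / dur
  n_samples <- as.integer(nrec * spr[1])
  data <- matrix(0, nch, n_samples)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, endian = "little")
      if (length(dig) < spr[1])
        stop("malformed EDF: data records shorter than the header declares")
      scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      data[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin_[i]) * scale + pmin_[i]
    }
  }
  sensor_recording(data, fs_hz = fs, channel_labels = labs)
}
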