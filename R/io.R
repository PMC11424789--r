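#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters with their documented
#' defaults. `validate_config()` rejects unknown keys, so typos in config
#' files fail loudly.
#'
#' @return named list:
#' \describe{
#'   \item{highpass_hz}{high-pass cutoff, Hz (0.5).}
#'   \item{bad_channel_z}{robust z threshold for bad channels (4).}
#'   \item{ica_corr_thresh}{|correlation| above which an independent
#'     component is removed (0.7).}
#'   \item{n_ica_comp}{maximum ICA components (20).}
#'   \item{n_epochs, epoch_s}{epochs per patient (10) and epoch length,
#'     seconds (5).}
#'   \item{lambda_reg, depth_gamma}{minimum-norm regularisation (`NULL` =
#'     SNR-derived) and depth weighting exponent (0.5).}
#'   \item{mvar_order}{MVAR model order (40).}
#'   \item{target_fs_hz, literal_fs}{region series are decimated to
#'     `target_fs_hz` (250) before fitting unless `literal_fs` is `TRUE`,
#'     in which case the native rate is used as-is.}
#'   \item{freq_min_hz, freq_max_hz, freq_step_hz}{PDC grid (0.5-45 by
#'     0.5 Hz).}
#'   \item{pdc_variant}{`"pdc"`, `"gpdc"` or `"sq"`.}
#'   \item{density}{proportional graph threshold (0.15).}
#'   \item{seed}{base seed for the seeded stages (1).}
#' }
#' @export
default_config <- function() {
  list(highpass_hz = 0.5, bad_channel_z = 4, ica_corr_thresh = 0.7,
       n_ica_comp = 20L, n_epochs = 10L, epoch_s = 5,
       lambda_reg = NULL, depth_gamma = 0.5,
       mvar_order = 40L, target_fs_hz = 250, literal_fs = FALSE,
       freq_min_hz = 0.5, freq_max_hz = 45, freq_step_hz = 0.5,
       pdc_variant = "pdc", density = 0.15, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fills unspecified keys with defaults and rejects unknown keys.
#'
#' @param config named list of overrides (possibly partial).
#' @return the completed configuration list.
#' @export
validate_config <- function(config = list()) {
  defs <- default_config()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  out <- utils::modifyList(defs, config, keep.null = TRUE)
  stopifnot(out$highpass_hz > 0, out$mvar_order >= 1,
            out$density > 0, out$density <= 1,
            out$pdc_variant %in% c("pdc", "gpdc", "sq"),
            out$freq_min_hz > 0, out$freq_max_hz > out$freq_min_hz)
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the [default_config()] keys.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Read a recording from EDF or delimited text
#'
#' EDF files (`.edf`) are read directly. Any other extension is treated
#' as a delimited numeric matrix (channels x samples, no header) and
#' requires a YAML sidecar `<path>.yaml` with at least `fs_hz` and
#' optionally `channel_labels`.
#'
#' @param path recording file.
#' @return a [sensor_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("recording not found: %s", path))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar metadata file: %s", sidecar))
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs_hz)) stop("sidecar must define fs_hz")
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  sensor_recording(m, fs_hz = meta$fs_hz,
                   channel_labels = meta$channel_labels %||%
                     sprintf("E%03d", seq_len(nrow(m))))
}

#' Read a patient manifest
#'
#' @param path TSV with columns `patient_id`, `group`, `soz_region`,
#'   `recording_path` (and optionally `truth_path`, `seed`). Paths are
#'   interpreted relative to the manifest's directory.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "soz_region", "recording_path")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols) > 0)
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(mf$patient_id)) stop("manifest patient ids must be unique")
  bad <- setdiff(unique(mf$group), c("seizure_free", "non_seizure_free"))
  if (length(bad) > 0)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  root <- dirname(path)
  mf$recording_path <- ifelse(grepl("^/", mf$recording_path),
                              mf$recording_path,
                              file.path(root, mf$recording_path))
  mf
}

#' Write a synthetic cohort to disk
#'
#' One EDF file per patient plus `manifest.tsv`, a `truth/` directory of
#' ground-truth coefficient tensors in long TSV form
#' (`lag`, `target`, `source`, `value`) with innovation covariances, and
#' the lead field (`leadfield.tsv` + `source_map.tsv`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort$patients) {
    edf <- file.path(dir, paste0(p$patient_id, ".edf"))
    write_edf(p$recording, edf)
    tr <- p$truth
    idx <- which(array(TRUE, dim(tr$coeffs)), arr.ind = TRUE)
    truth_df <- data.frame(lag = idx[, 3], target = idx[, 1],
                           source = idx[, 2], value = as.vector(tr$coeffs))
    tp <- file.path(dir, "truth", paste0(p$patient_id, "_coeffs.tsv"))
    utils::write.table(truth_df, tp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(tr$noise_cov,
                       file.path(dir, "truth",
                                 paste0(p$patient_id, "_noise_cov.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = p$patient_id, group = p$group, soz_region = p$soz_region,
      recording_path = basename(edf),
      truth_path = file.path("truth", basename(tp)), seed = p$seed)
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$lead_field$gain, file.path(dir, "leadfield.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(source_idx = seq_along(cohort$lead_field$source_region_map),
               region = cohort$lead_field$source_region_map,
               sign = cohort$lead_field$source_signs),
    file.path(dir, "source_map.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Read a lead field written by [write_cohort()]
#'
#' @param gain_path delimited matrix of gains (sensors x sources).
#' @param map_path TSV with columns `source_idx`, `region` and optionally
#'   `sign`.
#' @return a `lead_field` list.
#' @export
read_lead_field <- function(gain_path, map_path) {
  gain <- as.matrix(utils::read.delim(gain_path, header = FALSE))
  dimnames(gain) <- NULL
  mp <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  stopifnot(all(c("source_idx", "region") %in% names(mp)))
  mp <- mp[order(mp$source_idx), ]
  if (ncol(gain) != nrow(mp))
    stop("lead field column count does not match the source map")
  structure(list(gain = gain, source_region_map = mp$region,
                 source_signs = mp$sign %||% rep(1, nrow(mp))),
            class = "lead_field")
}
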