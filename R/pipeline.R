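#' Analyze a single patient recording
#'
#' Runs the per-patient stages end to end: zero-phase high-pass filter,
#' bad-channel detection (bad channels are dropped, not interpolated, to
#' avoid the rank deficiency interpolation would introduce into the MVAR
#' fit), ICA artifact removal (when reference waveforms are attached),
#' clean-epoch extraction, weighted minimum-norm inversion, region
#' aggregation, optional decimation, per-epoch Nuttall-Strand MVAR +
#' PDC, band averaging, inflow/outflow, and per-band graph metrics.
#'
#' @param recording a [sensor_recording()].
#' @param leadfield the [lead_field()] used for the inverse.
#' @param soz_region SOZ region index for feature extraction.
#' @param config a validated configuration, see [default_config()].
#' @param patient_id,group metadata carried into the feature table.
#' @return list with `features` (long data.frame), `band_conn`, `flow`,
#'   `metrics_per_band`, `bad_channels`, `fs_analysis`.
#' @export
analyze_recording <- function(recording, leadfield, soz_region,
                              config = validate_config(),
                              patient_id = "P000", group = "seizure_free") {
  rec <- highpass_filter(recording, config$highpass_hz)
  rec$bad_channels <- detect_bad_channels(rec, config$bad_channel_z)
  if (!is.null(rec$artifact_refs))
    rec <- remove_artifact_components(rec, config$ica_corr_thresh,
                                      seed = config$seed,
                                      n_comp = min(config$n_ica_comp,
                                                   sum(!(rec$channel_labels %in%
                                                           rec$bad_channels))))
  eps <- extract_epochs(rec, config$n_epochs, config$epoch_s)
  good <- !(rec$channel_labels %in% rec$bad_channels)
  lf_good <- leadfield
  lf_good$gain <- leadfield$gain[good, , drop = FALSE]
  op <- compute_wmne_operator(lf_good, lambda_reg = config$lambda_reg,
                              depth_gamma = config$depth_gamma)
  src <- apply_inverse(eps, op)
  reg <- aggregate_regions(src, leadfield$source_region_map)
  if (!config$literal_fs && reg$fs_hz > config$target_fs_hz) {
    fac <- reg$fs_hz / config$target_fs_hz
    if (abs(fac - round(fac)) > 1e-9)
      stop(sprintf("sampling rate %g Hz is not an integer multiple of target_fs_hz %g",
                   reg$fs_hz, config$target_fs_hz))
    reg <- decimate_epochs(reg, round(fac))
  }
  grid <- seq(config$freq_min_hz, config$freq_max_hz, by = config$freq_step_hz)
  grid <- grid[grid < reg$fs_hz / 2]
  spectra <- lapply(seq_len(dim(reg$epochs)[1]), function(e) {
    fit <- fit_mvar_nuttall_strand(
      matrix(reg$epochs[e, , ], dim(reg$epochs)[2]), config$mvar_order)
    pdc_spectrum(fit, grid, reg$fs_hz, variant = config$pdc_variant)
  })
  conn <- band_average(spectra)
  flow <- inflow_outflow(conn)
  colnames(flow$inflow) <- colnames(flow$outflow) <- names(conn)
  metrics <- lapply(conn, function(m)
    node_metrics(threshold_network(m, config$density)))
  feats <- extract_soz_features(flow, metrics, soz_region,
                                patient_id, group)
  list(features = feats, band_conn = conn, flow = flow,
       metrics_per_band = metrics, bad_channels = rec$bad_channels,
       fs_analysis = reg$fs_hz)
}

#' Analyze a synthetic cohort in memory
#'
#' Applies [analyze_recording()] to every patient of a
#' [generate_cohort()] result and runs the group comparison.
#'
#' @param cohort a `cohort_dataset`.
#' @param config pipeline configuration (see [default_config()]); epoch
#'   settings default to the cohort spec's.
#' @return list with `features` (all patients), `stats`
#'   (the 32-row [compare_groups()] table) and `patient_results`.
#' @export
analyze_cohort <- function(cohort, config = list()) {
  spec <- cohort$spec
  config <- validate_config(utils::modifyList(
    list(n_epochs = spec$n_epochs, epoch_s = spec$epoch_s), config))
  res <- lapply(cohort$patients, function(p)
    analyze_recording(p$recording, cohort$lead_field, p$soz_region, config,
                      patient_id = p$patient_id, group = p$group))
  features <- do.call(rbind, lapply(res, `[[`, "features"))
  list(features = features, stats = compare_groups(features),
       patient_results = res)
}

#' Run the file-based analysis pipeline
#'
#' Reads a patient manifest, analyzes every recording and writes, per
#' patient, the band connectivity matrices and flow/node metrics as TSV,
#' and at cohort level `features.tsv`, the 32-row `group_stats.tsv`,
#' `boxplots.json`, a log file and a frozen copy of the configuration
#' (`config.yaml`). A failing patient is logged and skipped; remaining
#' patients are still processed and the failure is reported in the return
#' value (the command-line wrapper exits non-zero in that case).
#'
#' @param manifest_path path to a manifest TSV (see [read_manifest()]).
#' @param leadfield_path,source_map_path lead-field files (see
#'   [read_lead_field()]).
#' @param out_dir output directory, created if needed.
#' @param config configuration overrides (list or path to YAML).
#' @return invisibly, a list with `features`, `stats`, `failed`
#'   (named list of error messages) and `out_dir`.
#' @export
run_pipeline <- function(manifest_path, leadfield_path, source_map_path,
                         out_dir, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  mf <- read_manifest(manifest_path)
  lf <- read_lead_field(leadfield_path, source_map_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                       sprintf(...)),
                               file = logf, append = TRUE)
  cfg_out <- config
  cfg_out$lambda_reg <- if (is.null(config$lambda_reg)) "auto" else config$lambda_reg
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  logline("pipeline start: %d patients, config hash %s", nrow(mf),
          substr(digest_config(config), 1, 12))
  features <- list()
  failed <- list()
  for (k in seq_len(nrow(mf))) {
    pid <- mf$patient_id[k]
    res <- tryCatch({
      rec <- read_recording(mf$recording_path[k])
      analyze_recording(rec, lf, mf$soz_region[k], config,
                        patient_id = pid, group = mf$group[k])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[pid]] <- conditionMessage(res)
      logline("patient %s FAILED: %s", pid, conditionMessage(res))
      next
    }
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (b in names(res$band_conn))
      utils::write.table(res$band_conn[[b]],
                         file.path(pdir, sprintf("conn_%s.tsv", b)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(res$features, file.path(pdir, "features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (b in names(res$metrics_per_band))
      utils::write.table(res$metrics_per_band[[b]],
                         file.path(pdir, sprintf("node_metrics_%s.tsv", b)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    features[[pid]] <- res$features
    logline("patient %s done (%d bad channels, analysis fs %g Hz)",
            pid, length(res$bad_channels), res$fs_analysis)
  }
  features <- do.call(rbind, features)
  stats_tbl <- NULL
  if (!is.null(features)) {
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stats_tbl <- tryCatch(compare_groups(features), error = function(e) {
      logline("group stats FAILED: %s", conditionMessage(e))
      NULL
    })
  }
  if (!is.null(stats_tbl)) {
    utils::write.table(stats_tbl, file.path(out_dir, "group_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    box <- list()
    for (r in seq_len(nrow(stats_tbl))) {
      m <- stats_tbl$measure[r]; b <- stats_tbl$band[r]
      sel <- features$measure == m & features$band == b
      vals_sf <- features$value[sel & features$group == "seizure_free"]
      vals_nsf <- features$value[sel & features$group == "non_seizure_free"]
      vals_sf <- vals_sf[is.finite(vals_sf)]
      vals_nsf <- vals_nsf[is.finite(vals_nsf)]
      box[[paste(m, b, sep = "_")]] <- list(
        seizure_free = if (length(vals_sf)) boxplot_summary(vals_sf),
        non_seizure_free = if (length(vals_nsf)) boxplot_summary(vals_nsf))
    }
    jsonlite::write_json(box, file.path(out_dir, "boxplots.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  logline("pipeline end: %d analyzed, %d failed",
          nrow(mf) - length(failed), length(failed))
  invisible(list(features = features, stats = stats_tbl, failed = failed,
                 out_dir = out_dir))
}

digest_config <- function(config) {
  s <- yaml::as.yaml(config[order(names(config))])
  # small stable checksum without extra dependencies
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
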