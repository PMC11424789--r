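#' Network archetypes for synthetic epileptic source networks
#'
#' Two qualitative connectivity archetypes for the region containing the
#' seizure onset zone (SOZ), operationalising the contrast between
#' surgical-outcome groups: `isolated_soz` has weak couplings into the SOZ
#' and a small, densely interconnected SOZ-adjacent cluster (structured,
#' clustered network); `diffuse_soz` has strong couplings into the SOZ
#' from many regions and no local cluster (extensive, scattered network).
#'
#' @param label `"isolated_soz"` or `"diffuse_soz"`.
#' @param soz_in_gain coupling gain on edges into the SOZ region. Defaults:
#'   0.05 (isolated) / 0.35 (diffuse); the isolated default is strictly
#'   below the diffuse one by construction.
#' @param soz_out_gain gain on edges out of the SOZ (default 0.25, both).
#' @param intra_cluster_gain gain among the SOZ-adjacent cluster members
#'   (default 0.35 isolated, 0 diffuse).
#' @param n_in_sources number of regions sending edges into the SOZ
#'   (default 3 isolated, 8 diffuse).
#' @param band_center_hz oscillation frequency (Hz) assigned to the SOZ
#'   region's own resonator; default 2.5 (delta), reflecting pathological
#'   slowing of the epileptogenic region.
#' @return a `network_archetype` list.
#' @export
network_archetype <- function(label = c("isolated_soz", "diffuse_soz"),
                              soz_in_gain = NULL, soz_out_gain = 0.25,
                              intra_cluster_gain = NULL, n_in_sources = NULL,
                              band_center_hz = 2.5) {
  label <- match.arg(label)
  if (is.null(soz_in_gain))
    soz_in_gain <- if (label == "isolated_soz") 0.05 else 0.35
  if (is.null(intra_cluster_gain))
    intra_cluster_gain <- if (label == "isolated_soz") 0.35 else 0
  if (is.null(n_in_sources))
    n_in_sources <- if (label == "isolated_soz") 3L else 8L
  stopifnot(soz_in_gain >= 0, soz_out_gain >= 0, intra_cluster_gain >= 0)
  structure(list(label = label, soz_in_gain = soz_in_gain,
                 soz_out_gain = soz_out_gain,
                 intra_cluster_gain = intra_cluster_gain,
                 n_in_sources = as.integer(n_in_sources),
                 band_center_hz = band_center_hz),
            class = "network_archetype")
}

#' Cohort specification for the synthetic generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: two
#' outcome groups of equal size, 12 source regions, 1000 Hz sampling and
#' ten artifact-free 5 s epochs per patient, mixed to 64 sensors (256
#' available via this argument).
#'
#' @param n_per_group patients per group (default 10).
#' @param n_regions number of source regions (default 12).
#' @param fs_hz sampling rate in Hz (default 1000).
#' @param n_epochs clean epochs per patient (default 10).
#' @param epoch_s epoch length in seconds (default 5); `epoch_s * fs_hz`
#'   must be integral.
#' @param n_sensors sensor count (default 64).
#' @param sources_per_region dipole sources per region in the lead field
#'   (default 2).
#' @param snr_db sensor signal-to-noise ratio in dB (default 10).
#' @param artifacts inject blink/ECG-like artifact bursts on flagged
#'   segments (default `TRUE`).
#' @param coupling_jitter_sd log-normal sd of per-edge gain jitter across
#'   patients (default 0.2).
#' @param background_density probability of a weak background coupling
#'   between two non-SOZ regions (default 0.15).
#' @param background_gain gain of background couplings (default 0.10).
#' @param seed master seed; per-patient seeds are derived from it
#'   deterministically, so a cohort is a pure function of its spec.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 10L, n_regions = 12L, fs_hz = 1000,
                        n_epochs = 10L, epoch_s = 5, n_sensors = 64L,
                        sources_per_region = 2L, snr_db = 10,
                        artifacts = TRUE, coupling_jitter_sd = 0.2,
                        background_density = 0.15, background_gain = 0.10,
                        seed = 1L) {
  stopifnot(n_per_group >= 1, n_regions >= 3, fs_hz > 0, n_epochs >= 1,
            epoch_s > 0, n_sensors >= 1, sources_per_region >= 1)
  if (abs(epoch_s * fs_hz - round(epoch_s * fs_hz)) > 1e-9)
    stop("epoch_s * fs_hz must be an integer number of samples")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_regions = as.integer(n_regions), fs_hz = fs_hz,
                 n_epochs = as.integer(n_epochs), epoch_s = epoch_s,
                 n_sensors = as.integer(n_sensors),
                 sources_per_region = as.integer(sources_per_region),
                 snr_db = snr_db, artifacts = isTRUE(artifacts),
                 coupling_jitter_sd = coupling_jitter_sd,
                 background_density = background_density,
                 background_gain = background_gain,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic per-patient seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 1000003) * 1009 + k * 7919) %% 2147483647)
}

# oscillator band centers assigned round-robin to regions so that every
# analysis band has spectral content
band_centers_hz <- function() c(2.5, 6.5, 10.5, 21.5)

#' Build a ground-truth MVAR source network from an archetype
#'
#' Each region's diagonal block is a damped AR(2) resonator (pole modulus
#' 0.96) tuned to one of the four band centers (2.5, 6.5, 10.5, 21.5 Hz,
#' round-robin; the SOZ region uses the archetype's `band_center_hz`).
#' Off-diagonal couplings are two-tap kernels `gain * (0.6, 0.4)` placed
#' according to the archetype: `isolated_soz` puts weak edges into the SOZ
#' and dense edges among a small SOZ-adjacent cluster; `diffuse_soz` puts
#' strong edges into the SOZ from many regions and no cluster. Weak
#' background couplings are scattered among the remaining regions. Each
#' edge gain receives a seeded log-normal jitter. Stability is enforced by
#' geometrically down-scaling all cross-couplings (factor 0.95, at most
#' 200 iterations) until the companion spectral radius is at most 0.97.
#'
#' @param n_regions number of regions (>= 3).
#' @param archetype a [network_archetype()].
#' @param soz_region SOZ region index in `1..n_regions`.
#' @param spec a [cohort_spec()] (supplies `fs_hz` and coupling
#'   configuration).
#' @param seed integer seed for edge placement and jitter.
#' @return a stationary [mvar_model()] of order 2 with attributes
#'   `soz_region` and `archetype`.
#' @export
build_archetype_mvar <- function(n_regions, archetype, soz_region,
                                 spec = cohort_spec(), seed = 1L) {
  stopifnot(n_regions >= 3, soz_region >= 1, soz_region <= n_regions)
  fs <- spec$fs_hz
  rho <- 0.96
  centers <- band_centers_hz()[(seq_len(n_regions) - 1) %% 4 + 1]
  centers[soz_region] <- archetype$band_center_hz
  A <- array(0, c(n_regions, n_regions, 2))
  th <- 2 * pi * centers / fs
  for (i in seq_len(n_regions)) {
    A[i, i, 1] <- 2 * rho * cos(th[i])
    A[i, i, 2] <- -rho^2
  }
  gains <- withr::with_seed(seed, {
    G <- matrix(0, n_regions, n_regions)  # G[i, j]: coupling j -> i
    others <- setdiff(seq_len(n_regions), soz_region)
    if (archetype$label == "isolated_soz") {
      csize <- min(archetype$n_in_sources, n_regions - 1)
      cluster <- ((soz_region - 1 + seq_len(csize)) %% n_regions) + 1
      cluster <- setdiff(cluster, soz_region)
      G[soz_region, cluster] <- archetype$soz_in_gain
      G[cluster, soz_region] <- archetype$soz_out_gain
      for (a in cluster) for (b in cluster)
        if (a != b) G[a, b] <- archetype$intra_cluster_gain
      protected <- cluster
    } else {
      nin <- min(archetype$n_in_sources, n_regions - 1)
      src <- sample(others, nin)
      G[soz_region, src] <- archetype$soz_in_gain
      dst <- sample(others, min(3L, n_regions - 1))
      G[dst, soz_region] <- archetype$soz_out_gain
      protected <- integer(0)
    }
    for (i in others) for (j in others) {
      if (i == j || G[i, j] != 0) next
      if (i %in% protected && j %in% protected) next
      if (stats::runif(1) < spec$background_density)
        G[i, j] <- spec$background_gain
    }
    jit <- matrix(exp(stats::rnorm(n_regions^2, 0, spec$coupling_jitter_sd)),
                  n_regions, n_regions)
    G * jit
  })
  for (i in seq_len(n_regions)) for (j in seq_len(n_regions)) {
    if (i == j || gains[i, j] == 0) next
    A[i, j, 1] <- gains[i, j] * 0.6
    A[i, j, 2] <- gains[i, j] * 0.4
  }
  model <- mvar_model(A)
  it <- 0
  off <- !diag(n_regions)
  while (spectral_radius(model) > 0.97) {
    it <- it + 1
    if (it > 200)
      stop("failed to stabilize archetype MVAR after 200 down-scalings; coupling gains are pathological")
    for (r in 1:2) model$coeffs[, , r][off] <- model$coeffs[, , r][off] * 0.95
  }
  attr(model, "soz_region") <- as.integer(soz_region)
  attr(model, "archetype") <- archetype$label
  model
}

#' Random lead field for sensor projection
#'
#' A synthetic gain matrix standing in for a BEM-derived forward model:
#' unit-norm random sensor topographies, `sources_per_region` sources per
#' region, with a random orientation sign per source.
#'
#' @param n_sensors number of sensors.
#' @param n_regions number of regions.
#' @param sources_per_region sources per region (default 2).
#' @param seed integer seed.
#' @return a `lead_field` list with `gain` (`n_sensors x n_sources`),
#'   `source_region_map` and `source_signs`.
#' @export
lead_field <- function(n_sensors, n_regions, sources_per_region = 2L,
                       seed = 1L) {
  n_sources <- n_regions * sources_per_region
  gain <- withr::with_seed(seed, {
    g <- matrix(stats::rnorm(n_sensors * n_sources), n_sensors, n_sources)
    sweep(g, 2, sqrt(colSums(g^2)), `/`)
  })
  signs <- withr::with_seed(seed + 1L,
    sample(c(-1, 1), n_sources, replace = TRUE))
  structure(list(gain = gain,
                 source_region_map = rep(seq_len(n_regions),
                                         each = sources_per_region),
                 source_signs = signs),
            class = "lead_field")
}

#' Project region time courses to sensors
#'
#' Each source carries its region's time course times its orientation
#' sign; sensors observe `gain %*% sources` plus white Gaussian noise
#' scaled so that `10*log10(signal power / noise power) = snr_db`.
#'
#' @param region_series `n_regions x n_samples` matrix.
#' @param leadfield a [lead_field()].
#' @param snr_db sensor SNR in dB; `Inf` means noiseless.
#' @param seed integer seed for the noise.
#' @return a [sensor_recording()] with channels labelled `"E001"`, ...
#' @export
project_to_sensors <- function(region_series, leadfield, snr_db = 10,
                               seed = 1L) {
  map <- leadfield$source_region_map
  if (max(map) > nrow(region_series))
    stop(sprintf("lead field maps sources to %d regions but series has %d rows",
                 max(map), nrow(region_series)))
  S <- region_series[map, , drop = FALSE] * leadfield$source_signs
  Y <- leadfield$gain %*% S
  if (is.finite(snr_db)) {
    psig <- mean(Y^2)
    sigma <- sqrt(psig / 10^(snr_db / 10))
    Y <- Y + withr::with_seed(seed,
      matrix(stats::rnorm(length(Y), 0, sigma), nrow(Y), ncol(Y)))
  }
  sensor_recording(Y, fs_hz = attr(region_series, "fs_hz") %||% NA_real_,
                   channel_labels = sprintf("E%03d", seq_len(nrow(Y))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# blink-like (smooth ~1 Hz transients) and ECG-like (~1.2 Hz biphasic
# spikes) reference waveforms, nonzero only inside flagged segments
artifact_waveforms <- function(n_samples, fs, mask, seed) {
  withr::with_seed(seed, {
    tgrid <- seq_len(n_samples) / fs
    blink <- numeric(n_samples)
    ecg <- numeric(n_samples)
    seg <- rle(mask)
    ends <- cumsum(seg$lengths)
    starts <- ends - seg$lengths + 1
    for (k in which(seg$values)) {
      idx <- starts[k]:ends[k]
      tt <- tgrid[idx] - tgrid[idx[1]]
      dur <- tt[length(tt)]
      for (ct in seq(0.3, dur, by = 1)) # ~1 Hz blink rate
        blink[idx] <- blink[idx] + exp(-((tt - ct) / 0.08)^2)
      for (ct in seq(0.15, dur, by = 1 / 1.2)) { # ~1.2 Hz heart rate
        ecg[idx] <- ecg[idx] + exp(-((tt - ct) / 0.015)^2) -
          0.4 * exp(-((tt - ct - 0.04) / 0.02)^2)
      }
    }
    rbind(blink = blink, ecg = ecg)
  })
}

#' Generate a seeded synthetic cohort
#'
#' Builds `2 * n_per_group` patients: the seizure-free group from the
#' `isolated_soz` archetype, the non-seizure-free group from
#' `diffuse_soz`. Each patient gets a deterministic derived seed, an SOZ
#' region sampled among the cortical (non-thalamic) regions, a
#' ground-truth stationary MVAR source network, simulated region activity
#' long enough for `n_epochs` non-overlapping clean epochs plus flagged
#' artifact segments, and a sensor projection through a shared lead field
#' with additive noise. When `spec$artifacts` is `TRUE`, blink- and
#' ECG-like transients are injected on fixed random topographies inside
#' the flagged segments and the reference waveforms are attached to the
#' recording (`artifact_refs`), so artifact removal can be validated
#' against known ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param archetypes named list with elements `seizure_free` and
#'   `non_seizure_free` giving the [network_archetype()] used for each
#'   group; defaults to `isolated_soz` / `diffuse_soz`. Passing the same
#'   archetype for both groups yields a null cohort.
#' @return a `cohort_dataset`: list with `patients` (each holding
#'   `patient_id`, `group`, `soz_region`, `recording`, `truth`, `seed`)
#'   and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            archetypes = list(
                              seizure_free = network_archetype("isolated_soz"),
                              non_seizure_free = network_archetype("diffuse_soz"))) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("seizure_free", "non_seizure_free") %in% names(archetypes)))
  fs <- spec$fs_hz
  ns_epoch <- round(spec$epoch_s * fs)
  if (spec$artifacts) {
    # layout: repeated [2-epoch clean block][1 s artifact burst]
    art_len <- round(fs)
    mask <- logical(0)
    remaining <- spec$n_epochs
    while (remaining > 0) {
      take <- min(2L, remaining)
      mask <- c(mask, rep(FALSE, take * ns_epoch), rep(TRUE, art_len))
      remaining <- remaining - take
    }
  } else {
    mask <- rep(FALSE, spec$n_epochs * ns_epoch)
  }
  n_total <- length(mask)
  lf <- lead_field(spec$n_sensors, spec$n_regions, spec$sources_per_region,
                   seed = derive_seed(spec$seed, 0L))
  n_cortical <- if (spec$n_regions == 12L) 10L else spec$n_regions
  groups <- rep(c("seizure_free", "non_seizure_free"), each = spec$n_per_group)
  patients <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    pseed <- derive_seed(spec$seed, k)
    soz <- withr::with_seed(pseed, sample.int(n_cortical, 1))
    truth <- build_archetype_mvar(spec$n_regions, archetypes[[groups[k]]],
                                  soz, spec, seed = pseed)
    series <- simulate_mvar(truth, n_total, burn_in = 500L,
                            seed = derive_seed(pseed, 1L))
    attr(series, "fs_hz") <- fs
    rec <- project_to_sensors(series, lf, spec$snr_db,
                              seed = derive_seed(pseed, 2L))
    rec$fs_hz <- fs
    if (spec$artifacts) {
      refs <- artifact_waveforms(n_total, fs, mask,
                                 seed = derive_seed(pseed, 3L))
      amp <- sqrt(mean(rec$data^2))
      topo <- withr::with_seed(derive_seed(pseed, 4L), {
        tb <- stats::rnorm(spec$n_sensors)
        te <- stats::rnorm(spec$n_sensors)
        cbind(tb / sqrt(sum(tb^2)), te / sqrt(sum(te^2)))
      })
      rec$data <- rec$data + (8 * amp) * topo[, 1] %o% refs["blink", ] +
        (4 * amp) * topo[, 2] %o% refs["ecg", ]
      rec$artifact_refs <- refs
    }
    attr(rec, "artifact_mask") <- mask
    patients[[k]] <- list(patient_id = sprintf("P%03d", k),
                          group = groups[k], soz_region = soz,
                          recording = rec, truth = truth, seed = pseed)
  }
  structure(list(patients = patients, spec = spec, lead_field = lf),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  g <- table(vapply(x$patients, `[[`, "", "group"))
  cat(sprintf("Synthetic cohort: %d patients (%s), %d regions, fs %g Hz\n",
              length(x$patients),
              paste(sprintf("%s n=%d", names(g), g), collapse = ", "),
              x$spec$n_regions, x$spec$fs_hz))
  invisible(x)
}
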