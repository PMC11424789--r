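test_that("zero coupling gains give a stable block-diagonal model", {
  arch <- network_archetype("isolated_soz", soz_in_gain = 0, soz_out_gain = 0,
                            intra_cluster_gain = 0)
  spec <- cohort_spec(background_density = 0, seed = 1)
  m <- build_archetype_mvar(6, arch, 2, spec, seed = 1)
  off <- !diag(6)
  for (r in 1:2) expect_true(all(m$coeffs[, , r][off] == 0))
  expect_lt(spectral_radius(m), 1)
})

test_that("default archetypes respect the stability margin (companion oracle)", {
  spec <- cohort_spec(seed = 1)
  for (lab in c("isolated_soz", "diffuse_soz")) {
    m <- build_archetype_mvar(12, network_archetype(lab), 3, spec, seed = 1)
    # independent check: eigenvalues of the explicitly assembled companion
    n <- 12; p <- 2
    C <- matrix(0, n * p, n * p)
    C[1:n, 1:n] <- m$coeffs[, , 1]
    C[1:n, (n + 1):(2 * n)] <- m$coeffs[, , 2]
    C[(n + 1):(2 * n), 1:n] <- diag(n)
    expect_lte(max(Mod(eigen(C, only.values = TRUE)$values)), 0.97)
  }
})

test_that("diffuse archetype has strictly more coupling into the SOZ", {
  spec <- cohort_spec(seed = 3)
  soz <- 4
  iso <- build_archetype_mvar(12, network_archetype("isolated_soz"), soz,
                              spec, seed = 3)
  dif <- build_archetype_mvar(12, network_archetype("diffuse_soz"), soz,
                              spec, seed = 3)
  in_sum <- function(m) {
    s <- 0
    for (r in 1:2) s <- s + sum(abs(m$coeffs[soz, -soz, r]))
    s
  }
  expect_gt(in_sum(dif), in_sum(iso))
  # the constructor's defaults encode the same ordering
  expect_lt(network_archetype("isolated_soz")$soz_in_gain,
            network_archetype("diffuse_soz")$soz_in_gain)
})

test_that("pathological gains fail to stabilize with a clear error", {
  arch <- network_archetype("diffuse_soz", soz_in_gain = 1e6,
                            soz_out_gain = 1e6)
  spec <- cohort_spec(background_gain = 1e6, background_density = 1, seed = 1)
  expect_error(build_archetype_mvar(12, arch, 1, spec, seed = 1),
               "stabilize")
})

test_that("sensor projection is exact for identity mixing without noise", {
  lf <- structure(list(gain = diag(4), source_region_map = 1:4,
                       source_signs = rep(1, 4)), class = "lead_field")
  x <- matrix(rnorm(4 * 100), 4)
  rec <- project_to_sensors(x, lf, snr_db = Inf, seed = 1)
  expect_equal(rec$data, x)
  # doubling the gain doubles the noiseless output
  lf2 <- lf; lf2$gain <- 2 * diag(4)
  rec2 <- project_to_sensors(x, lf2, snr_db = Inf, seed = 1)
  expect_equal(rec2$data, 2 * x)
})

test_that("projection noise realizes the requested SNR (0 dB within 0.5 dB)", {
  lf <- lead_field(16, 4, 2, seed = 2)
  x <- matrix(rnorm(4 * 20000), 4)
  clean <- project_to_sensors(x, lf, snr_db = Inf, seed = 3)$data
  noisy <- project_to_sensors(x, lf, snr_db = 0, seed = 3)$data
  snr_meas <- 10 * log10(mean(clean^2) / mean((noisy - clean)^2))
  expect_lt(abs(snr_meas - 0), 0.5)
})

test_that("default-shaped cohorts have the printed group structure", {
  spec <- cohort_spec(n_per_group = 10, n_regions = 12, fs_hz = 200,
                      n_epochs = 2, epoch_s = 1, n_sensors = 8, seed = 42)
  co <- generate_cohort(spec)
  groups <- vapply(co$patients, `[[`, "", "group")
  expect_length(co$patients, 20)
  expect_equal(sum(groups == "seizure_free"), 10)
  expect_equal(sum(groups == "non_seizure_free"), 10)
  expect_true(all(vapply(co$patients, function(p) p$truth$n_channels, 0) == 12))
  sozs <- vapply(co$patients, `[[`, 0L, "soz_region")
  expect_true(all(sozs >= 1 & sozs <= 12))
})

test_that("a cohort is a pure function of its spec", {
  spec <- cohort_spec(n_per_group = 2, n_regions = 5, fs_hz = 200,
                      n_epochs = 2, epoch_s = 1, n_sensors = 8, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (k in seq_along(a$patients)) {
    expect_identical(a$patients[[k]]$recording$data,
                     b$patients[[k]]$recording$data)
    expect_identical(a$patients[[k]]$truth$coeffs, b$patients[[k]]$truth$coeffs)
    expect_identical(a$patients[[k]]$soz_region, b$patients[[k]]$soz_region)
  }
})

test_that("group separation exists at ground-truth coefficient level", {
  spec <- cohort_spec(n_per_group = 50, n_regions = 12, fs_hz = 200,
                      n_epochs = 1, epoch_s = 0.5, n_sensors = 4,
                      snr_db = Inf, artifacts = FALSE, seed = 13)
  co <- generate_cohort(spec)
  in_sum <- vapply(co$patients, function(p) {
    soz <- p$soz_region
    sum(abs(p$truth$coeffs[soz, -soz, ]))
  }, 0)
  grp <- vapply(co$patients, `[[`, "", "group")
  expect_lt(mean(in_sum[grp == "seizure_free"]),
            mean(in_sum[grp == "non_seizure_free"]))
})
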