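test_that("high-pass filter rejects DC and preserves the passband", {
  fs <- 1000
  tt <- seq(0, 40, by = 1 / fs)
  rec <- sensor_recording(rbind(rep(1, length(tt)),
                                sin(2 * pi * 10 * tt),
                                sin(2 * pi * 0.05 * tt)), fs)
  f <- highpass_filter(rec, 0.5)
  mid <- 16000:24000   # away from edge transients
  # DC: output negligible relative to the unit input
  expect_lt(sqrt(mean(f$data[1, mid]^2)), 1e-6)
  # 10 Hz: amplitude matches the squared magnitude response of the design
  bf <- signal::butter(4, 0.5 / (fs / 2), type = "high")
  z <- exp(-1i * 2 * pi * 10 / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  expected_amp <- Mod(H)^2   # forward-backward pass squares the magnitude
  meas_amp <- max(abs(f$data[2, mid]))
  expect_lt(abs(meas_amp - expected_amp), 0.01)
  expect_gt(meas_amp, 0.99)
  expect_lt(meas_amp, 1.01)
  # 0.05 Hz: attenuated by more than 20 dB
  expect_lt(max(abs(f$data[3, mid])), 0.1)
})

test_that("filtering is zero-phase: a symmetric pulse keeps its center", {
  fs <- 500
  n <- 8001
  center <- 4001
  pulse <- exp(-((seq_len(n) - center) / 25)^2)
  rec <- sensor_recording(matrix(pulse, 1), fs)
  f <- highpass_filter(rec, 0.5)
  expect_equal(which.max(f$data[1, ]), center)
  # symmetry about the center (interior window)
  w <- 500
  left <- f$data[1, (center - w):(center - 1)]
  right <- rev(f$data[1, (center + 1):(center + w)])
  expect_lt(max(abs(left - right)), 1e-8)
})

test_that("cutoff at or above Nyquist is refused", {
  rec <- sensor_recording(matrix(rnorm(200), 2), 100)
  expect_error(highpass_filter(rec, 50), "Nyquist")
})

test_that("bad-channel detection flags outliers and flatlines only", {
  set.seed(21)
  X <- matrix(rnorm(20 * 4000), 20)
  rec <- sensor_recording(X, 500)
  expect_identical(detect_bad_channels(rec), character(0))
  X2 <- X
  X2[7, ] <- X2[7, ] * 100
  got <- detect_bad_channels(sensor_recording(X2, 500))
  expect_identical(got, rec$channel_labels[7])
  # direct robust z-score oracle agrees on which channel is extreme
  lv <- log(apply(X2, 1, var))
  z <- (lv - median(lv)) / mad(lv)
  expect_identical(which(abs(z) > 4), 7L)
  X3 <- X
  X3[3, ] <- 0
  expect_true(rec$channel_labels[3] %in%
                detect_bad_channels(sensor_recording(X3, 500)))
})

test_that("ICA removes an injected blink template but not clean data", {
  set.seed(31)
  n <- 12; N <- 6000; fs <- 200
  clean <- matrix(rnorm(n * N), n)
  tt <- seq_len(N) / fs
  blink <- numeric(N)
  for (ct in seq(0.5, max(tt) - 0.5, by = 1))
    blink <- blink + exp(-((tt - ct) / 0.08)^2)
  topo <- rnorm(n)
  X <- clean + 25 * topo %o% blink
  rec <- sensor_recording(X, fs, artifact_refs = matrix(blink, 1))
  out <- remove_artifact_components(rec, corr_thresh = 0.7, seed = 2)
  expect_lt(max(abs(cor(t(out$data), blink))), 0.2)
  expect_equal(dim(out$data), dim(X))
  # determinism
  out2 <- remove_artifact_components(rec, corr_thresh = 0.7, seed = 2)
  expect_identical(out$data, out2$data)
  # nothing correlated above threshold -> untouched data (the recording
  # holds a different non-Gaussian transient unrelated to the reference)
  other <- numeric(N)
  for (ct in seq(0.4, max(tt) - 0.4, by = 0.83))
    other <- other + exp(-((tt - ct) / 0.01)^2)
  X4 <- clean + 25 * rnorm(n) %o% other
  rec4 <- sensor_recording(X4, fs, artifact_refs = matrix(blink, 1))
  out4 <- remove_artifact_components(rec4, corr_thresh = 0.7, seed = 2)
  expect_equal(out4$data, X4, tolerance = 1e-6)
})

test_that("ICA reports a decomposition failure when nothing converges", {
  set.seed(32)
  X <- matrix(rnorm(10 * 4000), 10)
  expect_error(restflow:::fast_ica(X, n_comp = 10, seed = 1, max_iter = 1),
               "non-Gaussian")
})

test_that("ICA refuses to run without references or enough channels", {
  rec <- sensor_recording(matrix(rnorm(400), 4), 100)
  expect_error(remove_artifact_components(rec), "no artifact reference")
  rec2 <- sensor_recording(matrix(rnorm(400), 4), 100,
                           artifact_refs = matrix(rnorm(100), 1))
  expect_error(remove_artifact_components(rec2), "at least 8 good channels")
})

test_that("epoch extraction tiles clean data disjointly in temporal order", {
  fs <- 1000
  rec <- sensor_recording(matrix(rnorm(2 * 60000), 2), fs)
  eps <- extract_epochs(rec, n_epochs = 10, epoch_len_s = 5)
  expect_equal(dim(eps$epochs), c(10, 2, 5000))
  starts <- attr(eps, "starts")
  expect_equal(starts, seq(1, by = 5000, length.out = 10))
  # epochs reproduce the raw samples
  expect_equal(eps$epochs[3, , ], rec$data[, 10001:15000])
})

test_that("epochs avoid masked samples and insufficient data errors", {
  fs <- 100
  n <- 4000
  rec <- sensor_recording(matrix(rnorm(2 * n), 2), fs)
  mask <- rep(TRUE, n)
  mask[1:150] <- FALSE            # dirty prefix
  mask[500:560] <- FALSE          # dirty gap
  eps <- extract_epochs(rec, n_epochs = 3, epoch_len_s = 2, clean_mask = mask)
  starts <- attr(eps, "starts")
  expect_equal(starts[1], 151)
  for (s in starts) expect_true(all(mask[s:(s + 199)]))
  # only 40 s clean cannot yield 10 x 5 s
  rec2 <- sensor_recording(matrix(rnorm(4500), 1), 100)
  mask2 <- c(rep(TRUE, 4000), rep(FALSE, 500))
  expect_error(extract_epochs(rec2, 10, 5, mask2), "insufficient clean data")
})

test_that("bad channels are dropped from extracted epochs", {
  rec <- sensor_recording(matrix(rnorm(3 * 1000), 3), 100,
                          bad_channels = "E002")
  eps <- extract_epochs(rec, n_epochs = 2, epoch_len_s = 1)
  expect_equal(dim(eps$epochs)[2], 2)
  expect_identical(eps$channel_labels, c("E001", "E003"))
})
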