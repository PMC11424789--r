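test_that("an uncoupled model has diagonal PDC equal to one", {
  A <- array(0, c(3, 3, 1))
  diag(A[, , 1]) <- c(0.5, -0.3, 0.8)
  s <- pdc_spectrum(mvar_model(A), pdc_freq_grid(), 250)
  for (k in seq_along(s$freq_grid_hz)) {
    m <- s$values[k, , ]
    expect_equal(diag(m), rep(1, 3), tolerance = 1e-12)
    expect_equal(m[!diag(3)], rep(0, 6), tolerance = 1e-12)
  }
})

test_that("PDC at zero frequency matches the hand-evaluated closed form", {
  m <- mvar_model(array(c(0.5, 0.3, 0, 0.4), c(2, 2, 1)))
  # evaluate essentially at f = 0: Abar(0) = [[0.5, 0], [-0.3, 0.6]]
  s <- pdc_spectrum(m, 1e-12, 1000)
  expect_equal(s$values[1, 2, 1], 0.3 / sqrt(0.34), tolerance = 1e-12)
  expect_equal(s$values[1, 1, 1], 0.5 / sqrt(0.34), tolerance = 1e-12)
  expect_equal(s$values[1, 1, 2], 0, tolerance = 1e-12)
  expect_equal(s$values[1, 2, 2], 1, tolerance = 1e-12)
})

test_that("columns of squared PDC sum to one for random stable models", {
  for (seed in 1:10) {
    m <- random_stable_mvar(4, 3, seed)
    s <- pdc_spectrum(m, pdc_freq_grid(), 250)
    sums <- apply(s$values^2, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-10)
  }
})

test_that("gpdc and squared variants stay normalized and bounded", {
  m <- random_stable_mvar(3, 2, 99)
  m$noise_cov <- diag(c(1, 4, 0.25))
  g <- pdc_spectrum(m, pdc_freq_grid(), 250, variant = "gpdc")
  expect_lt(max(abs(apply(g$values^2, c(1, 3), sum) - 1)), 1e-10)
  sq <- pdc_spectrum(m, pdc_freq_grid(), 250, variant = "sq")
  expect_lt(max(abs(apply(sq$values, c(1, 3), sum) - 1)), 1e-10)
  expect_true(all(sq$values >= 0 & sq$values <= 1))
})

test_that("band averaging reproduces direct arithmetic on the grid", {
  m <- random_stable_mvar(3, 2, 17)
  grid <- seq(1, 4, by = 0.5)
  s <- pdc_spectrum(m, grid, 250)
  conn <- band_average(list(s), bands = list(delta = c(1, 4)))
  expect_equal(length(grid), 7)
  direct <- apply(s$values, c(2, 3), mean)
  expect_equal(conn$delta, direct, tolerance = 1e-12)
  # a constant spectrum averages to that constant in every band
  s2 <- s
  s2$values <- array(0.25, dim(s$values))
  c2 <- band_average(list(s2), bands = list(a = c(1, 2), b = c(3, 4)))
  expect_true(all(abs(c2$a - 0.25) < 1e-12) && all(abs(c2$b - 0.25) < 1e-12))
})

test_that("band averages are means over epochs and stay in [0, 1]", {
  m1 <- random_stable_mvar(3, 2, 21)
  m2 <- random_stable_mvar(3, 2, 22)
  grid <- pdc_freq_grid()
  s1 <- pdc_spectrum(m1, grid, 250)
  s2 <- pdc_spectrum(m2, grid, 250)
  both <- band_average(list(s1, s2))
  one <- band_average(list(s1))
  two <- band_average(list(s2))
  for (b in names(both)) {
    expect_equal(both[[b]], (one[[b]] + two[[b]]) / 2, tolerance = 1e-12)
    expect_true(all(both[[b]] >= 0 & both[[b]] <= 1))
  }
})

test_that("empty bands and mismatched grids are refused", {
  m <- random_stable_mvar(2, 1, 5)
  s <- pdc_spectrum(m, seq(10, 20, 0.5), 250)
  expect_error(band_average(list(s), bands = list(delta = c(1, 4))),
               "no grid frequency")
  s2 <- pdc_spectrum(m, seq(10, 20, 1), 250)
  expect_error(band_average(list(s, s2)), "same frequency grid")
})

test_that("inflow/outflow match the worked 2-region example", {
  m <- mvar_model(array(c(0.5, 0.3, 0, 0.4), c(2, 2, 1)))
  s <- pdc_spectrum(m, 1e-12, 1000)
  conn <- band_average(list(s), bands = list(dc = c(0, 1)))
  fl <- inflow_outflow(conn)
  expect_equal(unname(fl$inflow[2, 1]), 0.3 / sqrt(0.34), tolerance = 1e-6)
  expect_equal(unname(fl$outflow[1, 1]), 0.3 / sqrt(0.34), tolerance = 1e-6)
  expect_equal(unname(fl$inflow[1, 1]), 0, tolerance = 1e-12)
  # uncoupled network: all flows zero
  d <- array(0, c(2, 2, 1)); diag(d[, , 1]) <- 0.5
  s0 <- pdc_spectrum(mvar_model(d), 1e-12, 1000)
  fl0 <- inflow_outflow(band_average(list(s0), bands = list(dc = c(0, 1))))
  expect_true(all(fl0$inflow == 0) && all(fl0$outflow == 0))
})

test_that("inflow/outflow are permutation-equivariant and share their mean", {
  set.seed(12)
  conn <- list(b1 = matrix(runif(25), 5))
  fl <- inflow_outflow(conn)
  expect_equal(mean(fl$inflow), mean(fl$outflow), tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  connp <- list(b1 = conn$b1[perm, perm])
  flp <- inflow_outflow(connp)
  expect_equal(flp$inflow[, 1], fl$inflow[perm, 1], tolerance = 1e-12)
  expect_equal(flp$outflow[, 1], fl$outflow[perm, 1], tolerance = 1e-12)
  expect_error(inflow_outflow(list(b = matrix(1, 1, 1))), "2 regions")
})
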