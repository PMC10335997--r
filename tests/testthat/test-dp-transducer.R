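test_that("Boltzmann function hits its closed-form landmarks", {
  p <- boltzmann_params()
  expect_equal(boltzmann(2.6, p), 0.5)
  expect_equal(boltzmann(0, p), 1 / (1 + exp(0.28 * 2.6)), tolerance = 1e-12)
  expect_equal(boltzmann(0, p), 0.3256, tolerance = 2e-4)
  expect_gt(boltzmann(1e3, p), 1 - 1e-12)
  expect_lt(boltzmann(-1e3, p), 1e-12)
  x <- seq(-30, 30, by = 0.1)
  y <- boltzmann(x, p)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 0 & y < 1))
  # doubled slope or operating point keeps the output inside (0, 1)
  for (pp in list(boltzmann_params(a1 = 0.56), boltzmann_params(x1 = 5.2))) {
    yy <- boltzmann(x, pp)
    expect_true(all(yy > 0 & yy < 1))
  }
})

test_that("small-signal DP magnitude converges to the cubic-coefficient oracle", {
  p <- boltzmann_params()
  # analytic oracle: y'''(0) = a1^3 y (1-y) (1 - 6y + 6y^2) at y = y(0)
  y0 <- 1 / (1 + exp(p$a1 * p$x1))
  d3 <- p$a1^3 * y0 * (1 - y0) * (1 - 6 * y0 + 6 * y0^2)
  expect_lt(d3, 0)  # fixes the DP phase offset at 0.5 cycles
  for (amp in c(0.1, 0.05)) {
    d <- two_tone_drive(8220, 9000, amp, amp)
    dp <- simulate_two_tone_dp(d, p)
    expect_equal(Mod(dp), abs(d3) * amp^3 / 8, tolerance = 0.01)
  }
  expect_equal(Mod(simulate_two_tone_dp(two_tone_drive(8220, 9000, 0.1, 0.1), p)),
               1.91e-7, tolerance = 0.01)
})

test_that("small-signal DP phase is 2*phi1 - phi2 + 0.5 cycles", {
  p <- boltzmann_params()
  d0 <- two_tone_drive(8220, 9000, 0.05, 0.05, 0, 0)
  expect_equal(Arg(simulate_two_tone_dp(d0, p)) / (2 * pi), -0.5,
               tolerance = 1e-3)
  set.seed(7)
  for (i in 1:5) {
    p1 <- runif(1, -2, 2); p2 <- runif(1, -2, 2)
    d <- two_tone_drive(8220, 9000, 0.05, 0.08, p1, p2)
    got <- Arg(simulate_two_tone_dp(d, p)) / (2 * pi)
    want <- 2 * p1 - p2 + 0.5
    diffc <- (got - want) %% 1
    expect_lt(min(diffc, 1 - diffc), 1e-3)
  }
})

test_that("one tone alone produces no intermodulation", {
  d <- two_tone_drive(8220, 9000, 0.5, 0)
  expect_lt(Mod(simulate_two_tone_dp(d)), 1e-12)
})

test_that("DP grows with the f1 drive and saturates at large amplitudes", {
  amps <- c(0.5, 1, 2, 4, 8, 16)
  mags <- vapply(amps, function(a) {
    Mod(simulate_two_tone_dp(two_tone_drive(8220, 9000, a, 1)))
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
  # compressive beyond ~5 nm: last doubling gains < 1 dB/dB
  gain_db_per_db <- diff(20 * log10(mags)) / diff(20 * log10(amps))
  expect_lt(gain_db_per_db[length(gain_db_per_db)], 1)
  expect_gt(gain_db_per_db[1], 1.5)   # near-cubic (2 dB/dB) in the small regime
})

test_that("compiled kernel agrees with the pure-R reference", {
  d <- two_tone_drive(6950, 9000, 1.3, 0.8, -0.4, -1.1)
  a <- simulate_two_tone_dp(d, fs = 2e5)
  b <- dpoaewave:::simulate_two_tone_dp_r(d, fs = 2e5)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("commensurability and sampling-rate preconditions are enforced", {
  expect_error(simulate_two_tone_dp(two_tone_drive(8223, 9000, 1, 1)),
               "integer number")
  expect_error(simulate_two_tone_dp(two_tone_drive(8220, 9000, 1, 1), fs = 1e5),
               "fs")
  expect_error(two_tone_drive(9000, 8220, 1, 1), "f2 > f1")
  expect_error(two_tone_drive(4000, 9000, 1, 1), "positive")
})

test_that("the membrane low-pass matches its single-pole form", {
  lp <- lowpass_params()
  fc <- 9000 * 2^(-2.36)
  expect_equal(fc, 1753, tolerance = 0.5)
  expect_equal(Mod(lowpass_transfer(fc, 9000, lp)), 1 / sqrt(2),
               tolerance = 1e-9)
  f <- c(100, 1000, 5000, 20000)
  h <- lowpass_transfer(f, 9000, lp)
  expect_true(all(Mod(h) <= 1))
  ph <- Arg(h) / (2 * pi)
  expect_true(all(ph <= 0 & ph > -0.25))
  expect_equal(lowpass_transfer(5000, 9000, lowpass_params(enabled = FALSE)),
               1 + 0i)
})

test_that("local_dp composes the kernel and low-pass per position", {
  fr <- apical_fr_free()
  map <- default_map()
  x <- c(3.90, 3.99)
  f1 <- 8220; f2 <- 9000
  fl1 <- spatial_response(fr, map, f1, 50, positions = x)
  fl2 <- spatial_response(fr, map, f2, 50, positions = x)
  dps <- local_dp(fl1, fl2, map)
  expect_s3_class(dps, "local_dp_set")
  expect_equal(dps$f_dp, rep(2 * f1 - f2, 2))
  # composition identity at a single position
  d <- two_tone_drive(f1, f2, sqrt(2) * fl1$mag_nm[2], sqrt(2) * fl2$mag_nm[2],
                      fl1$phase_cycles[2], fl2$phase_cycles[2])
  manual <- simulate_two_tone_dp(d) *
    lowpass_transfer(2 * f1 - f2, cf_at(map, x[2]), lowpass_params())
  expect_equal(dps$dp_generated[2], manual, tolerance = 1e-12)
  # zero fields produce zero DPs
  fl1z <- fl1; fl1z$mag_nm <- rep(0, 2)
  fl2z <- fl2; fl2z$mag_nm <- rep(0, 2)
  expect_true(all(Mod(local_dp(fl1z, fl2z, map)$dp_generated) < 1e-15))
  # mismatched grids are rejected
  fl_bad <- spatial_response(fr, map, f1, 50, positions = c(1, 2))
  expect_error(local_dp(fl_bad, fl2, map), "position grid")
})

test_that("DP generation peaks basal to or at the f2 place within the overlap", {
  fr <- apical_fr_free()
  map <- default_map()
  f2 <- 9000
  f1 <- round_frequency(f2 / 1.095)
  fl1 <- spatial_response(fr, map, f1, 50)
  fl2 <- spatial_response(fr, map, f2, 50)
  dps <- local_dp(fl1, fl2, map)
  x_max <- dps$pos_mm[which.max(Mod(dps$dp_generated))]
  x2 <- place_of(map, f2)
  x1 <- place_of(map, f1)
  expect_lte(x_max, x2 + 0.15)   # at or basal of the f2 peak place
  expect_gte(x_max, x2 - 0.5)    # inside the f1-f2 overlap region
  expect_lte(x_max, x1)
})
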