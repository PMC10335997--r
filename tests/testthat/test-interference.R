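make_dps <- function(pos, dp_gen, dp_stapes = NULL, stapes_phase = NULL) {
  n <- length(pos)
  out <- data.frame(pos_mm = pos, f_dp = rep(6000, n))
  out$dp_generated <- rep_len(dp_gen, n)
  out$dp_stapes <- if (is.null(dp_stapes)) {
    rep(NA_complex_, n)
  } else rep_len(dp_stapes, n)
  if (!is.null(stapes_phase)) out$dp_stapes_phase <- stapes_phase
  class(out) <- c("local_dp_set", "data.frame")
  out
}

test_that("fast-wave propagation leaves the generated DPs untouched", {
  dps <- make_dps(c(1, 2, 3), complex(real = c(1, 2, 3), imaginary = c(0, 1, -1)))
  out <- propagate_to_stapes(dps, apical_fr_free(), default_map(),
                             propagation_options("fast_wave"))
  expect_identical(out$dp_stapes, out$dp_generated)
})

test_that("slow-wave propagation applies the weight magnitude and phase lag", {
  fr <- apical_fr_free()
  map <- default_map()
  x <- c(3.5, 3.99)
  dps <- make_dps(x, complex(real = c(1, 1), imaginary = 0))
  out <- propagate_to_stapes(dps, fr, map, propagation_options("slow_wave"))
  w <- spatial_response(fr, map, 6000, 40, positions = x)
  expect_equal(out$dp_stapes,
               out$dp_generated * w$mag_nm * exp(2i * pi * w$phase_cycles),
               tolerance = 1e-12)
  # velocity weighting multiplies by the radian DP frequency
  outv <- propagate_to_stapes(dps, fr, map,
                              propagation_options("slow_wave",
                                                  weighting = "velocity"))
  expect_equal(outv$dp_stapes, out$dp_stapes * 2 * pi * 6000, tolerance = 1e-9)
})

test_that("vector summation cancels antiphase components and adds coherent ones", {
  opt <- propagation_options()
  dps <- make_dps(c(1, 2), NA, complex(modulus = c(1, 1), argument = c(0, pi)))
  expect_equal(Mod(sum_dpoae(dps, opt)), 0, tolerance = 1e-12)
  dps5 <- make_dps(1:5, NA, complex(modulus = rep(2, 5), argument = 0.3))
  expect_equal(Mod(sum_dpoae(dps5, opt)), 10, tolerance = 1e-12)
  # zero-phase control sums magnitudes, an upper bound for any phase pattern
  set.seed(11)
  rnd <- make_dps(1:20, NA, complex(modulus = runif(20), argument = runif(20, 0, 2 * pi)))
  zp <- propagation_options(zero_phase_control = TRUE)
  expect_gte(Mod(sum_dpoae(rnd, zp)), Mod(sum_dpoae(rnd, opt)))
  expect_equal(Mod(sum_dpoae(rnd, zp)), sum(Mod(rnd$dp_stapes)), tolerance = 1e-12)
  expect_error(sum_dpoae(make_dps(numeric(0), complex(0)), opt), "empty")
})

test_that("phase spread is the unwrapped range over the 10 dB generation region", {
  one <- make_dps(1, 1 + 0i, 1 + 0i)
  expect_equal(phase_spread(one), 0)
  two <- make_dps(c(1, 2), complex(real = c(1, 1)),
                  complex(modulus = 1, argument = 2 * pi * c(-0.2, -0.9)),
                  stapes_phase = c(-0.2, -0.9))
  expect_equal(phase_spread(two), 0.7, tolerance = 1e-9)
  # positions outside the 10 dB region do not contribute
  three <- make_dps(c(1, 2, 3),
                    complex(modulus = c(1, 1, 0.01), argument = 0),
                    complex(modulus = 1, argument = 2 * pi * c(-0.2, -0.9, -5)),
                    stapes_phase = c(-0.2, -0.9, -5))
  expect_equal(phase_spread(three), 0.7, tolerance = 1e-9)
  expect_error(phase_spread(make_dps(1, 0 + 0i, 0 + 0i)), "zero")
})

test_that("the effective ratio grid stores the rounded-f1 arithmetic", {
  rep_res <- reproduction()
  rf <- rep_res$details$sweeps$slow_wave[["50"]]
  expect_length(rf$ratios, 35)
  expect_equal(rf$f1, round_frequency(9000 / seq(1.02, 1.87, by = 0.025)))
  expect_equal(rf$f_dp, 2 * rf$f1 - 9000)
  # invariant: f_dp = 2 (f2 / ratio) - f2 against the effective ratios
  expect_equal(rf$f_dp, 2 * rf$f2 / rf$ratios - rf$f2, tolerance = 1e-9)
  expect_error(ratio_function(apical_fr_free(), default_map(),
                              ratios = c(0.9, 1.1)), "1.02")
})

test_that("slow-wave ratio functions are bandpass at 40-70 dB SPL", {
  rep_res <- reproduction()
  for (l in c("40", "50", "60", "70")) {
    rf <- rep_res$details$sweeps$slow_wave[[l]]
    a <- dpoae_db_re_max(rf)
    i <- which.max(a)
    expect_gt(i, 1)
    expect_lt(i, length(a))
    expect_lte(a[1], -10)
    expect_lte(a[length(a)], -10)
  }
})

test_that("zero-phase control removes the bandpass: amplitude grows toward small ratios", {
  rep_res <- reproduction()
  rf <- rep_res$details$sweeps$zero_phase[["50"]]
  amp <- Mod(rf$dpoae)
  sel <- rf$ratios >= 1.05
  expect_true(all(diff(amp[sel]) < 0))
  # and it bounds the interfering sum from above (triangle inequality)
  slow <- rep_res$details$sweeps$slow_wave[["50"]]
  expect_true(all(amp >= Mod(slow$dpoae) - 1e-12))
})

test_that("fast-wave summation keeps a bandpass but is more broadly tuned", {
  rep_res <- reproduction()
  for (l in c("40", "50", "60", "70")) {
    rf <- rep_res$details$sweeps$fast_wave[[l]]
    a <- dpoae_db_re_max(rf)
    i <- which.max(a)
    expect_gt(i, 1); expect_lt(i, length(a))
    expect_lte(a[1], -10)
    expect_lte(a[length(a)], -10)
    q_fast <- rep_res$details$fast_tuning[[l]]$q10
    q_slow <- rep_res$details$slow_tuning[[l]]$q10
    expect_lt(q_fast, q_slow)
  }
})

test_that("modeled DPOAE Q10dB decreases monotonically from 40 to 70 dB SPL", {
  rep_res <- reproduction()
  q <- vapply(rep_res$details$slow_tuning, function(t) t$q10, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("low-pass removal and velocity weighting perturb Q10dB by <= 15% and keep the bandpass", {
  fr <- apical_fr_free()
  map <- default_map()
  base <- cached("variant_base", ratio_function(fr, map, level1 = 50))
  q_base <- ratio_function_tuning(base)$q10
  no_lp <- cached("variant_nolp",
                  ratio_function(fr, map, level1 = 50,
                                 lp = lowpass_params(enabled = FALSE)))
  vel <- cached("variant_vel",
                ratio_function(fr, map, level1 = 50,
                               opt = propagation_options(weighting = "velocity")))
  for (rf in list(no_lp, vel)) {
    a <- dpoae_db_re_max(rf)
    i <- which.max(a)
    expect_gt(i, 1); expect_lt(i, length(a))
    expect_lte(a[1], -6); expect_lte(a[length(a)], -10)
    expect_lt(abs(suppressWarnings(ratio_function_tuning(rf))$q10 - q_base) / q_base,
              0.15)
  }
})

test_that("locally generated DPs grow monotonically as f1 approaches f2", {
  fr <- apical_fr_free()
  map <- default_map()
  loc <- cached("local_rf",
                local_dp_ratio_function(fr, map, ratios = seq(1.02, 1.87, by = 0.05),
                                        level = 50))
  expect_true(all(is.finite(loc$amp) & loc$amp > 0))
  expect_gt(loc$amp[loc$ratio == min(loc$ratio)],
            loc$amp[which.min(abs(loc$ratio - 1.30))])
  # and it matches local_dp at the f2 peak position (composition identity)
  f1 <- round_frequency(9000 / 1.32)
  fl1 <- spatial_response(fr, map, f1, 50)
  fl2 <- spatial_response(fr, map, 9000, 50)
  dps <- local_dp(fl1, fl2, map)
  i2 <- which.max(fl2$mag_nm)
  j <- which.min(abs(loc$f1 - f1))
  expect_equal(loc$amp[j], Mod(dps$dp_generated[i2]), tolerance = 1e-9)
})

test_that("phase spread exceeds half a cycle just below the optimal ratio", {
  rep_res <- reproduction()
  rf <- rep_res$details$sweeps$slow_wave[["50"]]
  i_opt <- which.max(Mod(rf$dpoae))
  expect_gte(rf$spread_cycles[i_opt - 1], 0.5)
})
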