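test_that("the default apical response peaks at the CF at low level", {
  fr <- apical_fr()
  f_peak <- fr$freqs[which.max(fr$magnitude[match(30, fr$levels), ])]
  expect_lt(abs(log2(f_peak / 9000)), 0.1)
})

test_that("a passive profile is level-linear in normalized magnitude", {
  fr <- generate_frequency_response(site_profile(gain_max = 0),
                                    levels = c(30, 50, 70, 90))
  norm <- fr$magnitude / (20e-6 * 10^(fr$levels / 20))
  for (i in 2:4) expect_equal(norm[i, ], norm[1, ], tolerance = 1e-9)
})

test_that("the low-frequency tail grows 10 dB per 10 dB of level", {
  fr <- apical_fr()
  i <- which.min(abs(fr$freqs - 9000 / 4))
  g <- 20 * log10(fr$magnitude[match(40, fr$levels), i] /
                    fr$magnitude[match(30, fr$levels), i])
  expect_lt(abs(g - 10), 0.5)
})

test_that("magnitude curves are unimodal and the peak glides down with level", {
  for (fr in list(apical_fr(), middle_fr())) {
    peaks <- numeric(length(fr$levels))
    for (i in seq_along(fr$levels)) {
      m <- fr$magnitude[i, ]
      j <- which.max(m)
      expect_true(all(diff(m[seq_len(j)]) > 0))
      expect_true(all(diff(m[j:length(m)]) < 0))
      peaks[i] <- fr$freqs[j]
    }
    expect_true(all(diff(peaks) <= 0))
    shift <- log2(peaks[1] / peaks[length(peaks)])
    expect_lte(shift, fr$site$peak_shift_octaves + 0.05)
    expect_gte(shift, 0)   # grid quantization can absorb a small glide
  }
})

test_that("Q10dB decreases monotonically with stimulus level", {
  fr <- apical_fr()
  qs <- vapply(fr$levels, function(l) {
    q10(fr$freqs, fr$magnitude[match(l, fr$levels), ])$q10
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-9))
})

test_that("tail phase (middle ear removed) is level-insensitive below CF/2", {
  fr <- apical_fr_free()
  j <- which(fr$freqs <= 4500)
  spread <- apply(fr$phase[, j, drop = FALSE], 2, function(p) max(p) - min(p))
  expect_lt(max(spread), 0.05)
})

test_that("phase lags accumulate monotonically with frequency", {
  fr <- apical_fr_free()
  for (i in seq_along(fr$levels)) {
    expect_true(all(diff(fr$phase[i, ]) < 0))
  }
})

test_that("generation is deterministic", {
  a <- generate_frequency_response(apical_profile())
  b <- generate_frequency_response(apical_profile())
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$phase, b$phase)
})

test_that("calibration report reproduces the emulated summary statistics", {
  cal <- calibration_report(apical_fr())
  expect_equal(cal$gain_db, 41.1, tolerance = 0.025)
  expect_equal(cal$q10_ratio_40_75, 2, tolerance = 0.15)
  expect_equal(cal$phase_at_cf, -apical_fr()$site$phase_cycles_at_cf,
               tolerance = 0.15)
  expect_true(all(is.finite(unlist(cal[c("gain_db", "q10_ratio_40_75",
                                         "peak_shift_octaves", "phase_at_cf")]))))
})

test_that("a passive profile reports zero gain and flat Q ratio", {
  fr <- generate_frequency_response(site_profile(gain_max = 0))
  cal <- calibration_report(fr)
  expect_equal(cal$gain_db, 0, tolerance = 1e-9)
  expect_equal(cal$q10_ratio_40_75, 1, tolerance = 1e-9)
})

test_that("calibration requires the anchor levels", {
  fr <- generate_frequency_response(apical_profile(), levels = c(30, 50, 90))
  expect_error(calibration_report(fr), "40")
})

test_that("middle-turn tuning is at least 1.5x sharper than apical", {
  cal_a <- calibration_report(apical_fr())
  cal_m <- calibration_report(middle_fr())
  lv <- as.character(c(40, 50, 60, 70))
  ratio <- cal_m$q10_by_level[lv] / cal_a$q10_by_level[lv]
  expect_true(all(ratio >= 1.5))
})

test_that("generator rejects invalid grids", {
  p <- apical_profile()
  expect_error(generate_frequency_response(p, freqs = numeric(0)), "empty")
  expect_error(generate_frequency_response(p, freqs = c(-1, 1000)), "positive")
  expect_error(generate_frequency_response(p, freqs = c(2000, 1000)),
               "ascending")
  expect_error(generate_frequency_response(p, levels = c(5, 50)), "\\[10, 90\\]")
  expect_error(site_profile(cf_ref = -1), "positive")
  expect_error(site_profile(gain_max = -3), "gain_max")
})

test_that("response tables round-trip bit-exactly", {
  fr <- apical_fr()
  path <- tempfile(fileext = ".csv")
  write_response_table(fr, path)
  back <- read_response_table(path)
  expect_identical(back$freqs, fr$freqs)
  expect_identical(back$levels, fr$levels)
  expect_identical(back$magnitude, fr$magnitude)
  expect_identical(back$phase, fr$phase)
  expect_equal(back$site$cf_ref, fr$site$cf_ref)
  expect_equal(back$includes_middle_ear, fr$includes_middle_ear)
  unlink(path)
})

test_that("malformed response tables are rejected", {
  fr <- apical_fr()
  path <- tempfile(fileext = ".csv")
  write_response_table(fr, path)
  lines <- readLines(path)
  # missing phase column
  hdr_i <- grep("^freq_hz", lines)
  broken <- sub(",phase_cycles", "", lines)
  broken <- vapply(seq_along(broken), function(i) {
    if (i > hdr_i) sub(",[^,]*$", "", broken[i]) else broken[i]
  }, character(1))
  p2 <- tempfile(fileext = ".csv"); writeLines(broken, p2)
  expect_error(read_response_table(p2), "missing required columns")
  # duplicated (freq, level) rows
  p3 <- tempfile(fileext = ".csv")
  writeLines(c(lines, lines[hdr_i + 1]), p3)
  expect_error(read_response_table(p3), "duplicated")
  # non-rectangular grid
  p4 <- tempfile(fileext = ".csv")
  writeLines(lines[-(hdr_i + 1)], p4)
  expect_error(read_response_table(p4), "rectangular")
  unlink(c(path, p2, p3, p4))
})

test_that("the noise-floor operation is seeded and bounded", {
  fr <- apical_fr()
  expect_error(add_noise_floor(fr), "seed")
  a <- add_noise_floor(fr, 0.003, seed = 42)
  b <- add_noise_floor(fr, 0.003, seed = 42)
  expect_identical(a$magnitude, b$magnitude)
  c2 <- add_noise_floor(fr, 0.003, seed = 43)
  expect_false(identical(a$magnitude, c2$magnitude))
  # perturbation scale matches the requested floor
  expect_lt(max(abs(a$magnitude - fr$magnitude)), 0.003 * 6)
  expect_lt(max(abs(a$phase - fr$phase)), 0.5)
})
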