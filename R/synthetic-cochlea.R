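# Parametric generator of mouse-like single-tone cochlear frequency responses.
#
# The generator is a stand-in for averaged basilar-membrane (BM) measurements:
# magnitude (in dB) is the sum of a level-linear passive skirt and a
# compressive active gain window centred on the CF; phase is a monotone
# sigmoid accumulation of traveling-wave lag plus an optional pure middle-ear
# delay. All shape widths scale with 1/q_sharpness so that sharper (more
# basal) sites are produced by the same machinery.

# Fixed shape constants, calibrated once so the default apical profile
# reproduces the target summary statistics of the emulated data set
# (41.1 dB of compressive gain, Q10dB halving from 40 to 75 dB SPL, ~0.15
# octave downward peak shift, ~1.5 cycles of phase lag at CF). See the
# methods vignette for the calibration rationale.
.shape <- list(
  k_lo    = 16,   # passive skirt curvature, low side (dB/oct^2)
  delta_lo = 0.35, # low-side transition to linear tail (oct); tail slope k*delta
  k_hi    = 300,  # passive skirt curvature, high side (dB/oct^2)
  delta_hi = 0.4, # high-side transition (oct)
  sigma_lo = 0.50, # active window Lorentzian half-width below CF (oct)
  sigma_hi = 0.20, # active window Lorentzian half-width above CF (oct)
  w_phase_lo = 0.10, # phase transition width below CF (oct)
  w_phase_hi = 0.13, # phase transition width above CF (oct)
  eps_phase = 0.4, # passive floor of the near-CF phase slope (fraction of the
                   # low-level slope retained when the active gain is gone)
  alpha_narrow = 0.6, # weight of the narrow phase component
  wide_mult = 3,  # width multiplier of the broad phase component
  s_tail = 0.3,   # baseline tail phase slope (cycles/oct): waves keep moving
  nu_tail0 = -log2(9) # tail ramp anchor (phase ~0 at cf/9)
)

# Active gain (dB) at stimulus level L: full gain at <= 30 dB SPL, linear
# decline to zero at 90 dB SPL.
active_gain_db <- function(level, gain_max) {
  gain_max * pmin(pmax((90 - level) / 60, 0), 1)
}

# Passive skirt P(nu) in dB, peaking at nu = -peak_shift (nu = log2(f/cf)).
passive_skirt_db <- function(nu, peak_shift, q) {
  u <- nu + peak_shift
  lo <- u < 0
  out <- numeric(length(nu))
  out[lo] <- -.shape$k_lo * huber(q * u[lo], .shape$delta_lo)
  out[!lo] <- -.shape$k_hi * huber(q * u[!lo], .shape$delta_hi)
  out
}

# Unit-height asymmetric active window peaked at nu = 0. Lorentzian shape:
# parabolic near the top (sets the sharp low-level tuning) with heavy skirts
# (cochlear amplification tapers gradually, so near-CF shoulders stay high).
active_window <- function(nu, q) {
  sigma <- ifelse(nu < 0, .shape$sigma_lo, .shape$sigma_hi)
  1 / (1 + (q * nu / sigma)^2)
}

# Phase accumulation profile S(nu): 0 in the low-frequency tail, 1 at CF,
# saturating shortly above CF. Weighted sum of two asymmetric tanh sigmoids
# sharing a centre at CF: a narrow component (width w_lo / w_hi octaves below
# / above CF; the wave slowing sharply at its best place) and a broad
# component (widths scaled by `wide_mult`; the gradual group-delay build-up
# over the octave below CF). `scale` broadens all widths jointly (used for
# the level dependence).
tanh_sigmoid <- function(nu, w_lo, w_hi) {
  ifelse(nu < 0,
         1 + tanh(nu / (2 * w_lo)),
         1 + (w_hi / w_lo) * tanh(nu / (2 * w_hi)))
}

# `level_scale` broadens the narrow component (shallower near-CF slope as the
# active gain recedes); the broad component is level-independent so that tail
# phases stay level-insensitive. All widths shrink with site sharpness `q`.
phase_sigmoid <- function(nu, level_scale = 1, q = 1) {
  w_lo <- .shape$w_phase_lo / q
  w_hi <- .shape$w_phase_hi / q
  a <- .shape$alpha_narrow
  m <- .shape$wide_mult
  a * tanh_sigmoid(nu, w_lo * level_scale, w_hi * level_scale) +
    (1 - a) * tanh_sigmoid(nu, m * w_lo, m * w_hi)
}

#' Generate a synthetic single-tone frequency response
#'
#' Produces displacement magnitude (nm RMS) and unwrapped phase (cycles,
#' lags negative) on a frequency-by-level grid for one cochlear site. The
#' construction is deterministic: magnitude in dB is the sum of a passive
#' term (linear in stimulus level, broad asymmetric skirt peaking slightly
#' below CF) and an active term (gain declining linearly from full at 30 dB
#' SPL to zero at 90 dB SPL, concentrated in a narrow window at CF), so that
#' tail responses grow 1 dB/dB while CF responses grow compressively and the
#' peak glides downward with increasing level. Phase accumulates lag
#' monotonically with frequency via a sigmoid in log-frequency, with a
#' slightly shallower near-CF slope at high levels, plus a pure middle-ear
#' delay when `include_middle_ear` is set.
#'
#' @param profile A [site_profile()].
#' @param freqs Ascending stimulus frequencies in Hz. Default mirrors a
#'   1-15 kHz sweep in 0.5 kHz steps for a 9 kHz site, scaled to the
#'   profile's CF.
#' @param levels Ascending stimulus levels in dB SPL, within \[10, 90\].
#' @param include_middle_ear If `TRUE`, phases include the forward middle-ear
#'   delay (as in ear-canal-referenced measurements). Remove it with
#'   [remove_middle_ear_delay()] before spatial extrapolation.
#' @return A `frequency_response`: list with `site`, `freqs`, `levels`,
#'   `magnitude` and `phase` matrices (levels x freqs) and the
#'   `includes_middle_ear` flag.
#' @export
generate_frequency_response <- function(profile,
                                        freqs = NULL,
                                        levels = seq(10, 90, by = 5),
                                        include_middle_ear = TRUE) {
  stopifnot(inherits(profile, "site_profile"))
  if (is.null(freqs)) {
    freqs <- seq(1000, 15000, by = 500) * profile$cf_ref / 9000
  }
  if (length(freqs) == 0 || length(levels) == 0) stop("empty frequency or level grid")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly ascending")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly ascending")
  if (any(levels < 10 | levels > 90)) stop("levels must lie within [10, 90] dB SPL")

  q <- profile$q_sharpness
  nu <- log2(freqs / profile$cf_ref)
  P <- passive_skirt_db(nu, profile$peak_shift_octaves, q)
  W <- active_window(nu, q)
  G <- active_gain_db(levels, profile$gain_max)

  # dB re 1 nm, anchored so the CF response at 30 dB SPL is cf_mag_30_nm.
  anchor <- db(profile$cf_mag_30_nm) - (passive_skirt_db(0, profile$peak_shift_octaves, q) +
                                          active_gain_db(30, profile$gain_max))
  mag_db <- outer(levels - 30, P, function(l, p) l + p) + outer(G, W) + anchor
  magnitude <- undb(mag_db)

  # Phase: the near-CF slope of the narrow component tracks the active gain
  # (steep at low level, relaxing toward a passive floor as gain recedes).
  g_frac <- if (profile$gain_max > 0) G / profile$gain_max else rep(1, length(levels))
  eps <- .shape$eps_phase
  scale_l <- 1 / (eps + (1 - eps) * g_frac)
  # level-independent baseline lag: traveling waves accumulate a slow, steady
  # phase slope well basal of their peak (the tail is never phase-frozen)
  tail_lag <- .shape$s_tail * q * pmax(nu - .shape$nu_tail0 / q, 0)
  # the sigmoid carries whatever CF lag the baseline ramp does not
  sig_amp <- profile$phase_cycles_at_cf - .shape$s_tail * (-.shape$nu_tail0)
  if (sig_amp <= 0) {
    stop("phase_cycles_at_cf too small for the baseline tail lag (need > ",
         round(.shape$s_tail * (-.shape$nu_tail0), 2), " cycles)")
  }
  phase <- -sig_amp *
    t(vapply(scale_l, function(s) phase_sigmoid(nu, s, q), numeric(length(nu)))) -
    outer(rep(1, length(levels)), tail_lag)
  if (include_middle_ear) {
    phase <- phase - outer(rep(1, length(levels)), freqs * profile$middle_ear_delay)
  }

  structure(
    list(
      site = profile,
      freqs = freqs,
      levels = levels,
      magnitude = magnitude,
      phase = phase,
      includes_middle_ear = include_middle_ear
    ),
    class = "frequency_response"
  )
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %s, CF %.3g kHz: %d freqs x %d levels%s\n",
              x$site$structure_tag, x$site$cf_ref / 1000, length(x$freqs),
              length(x$levels),
              if (x$includes_middle_ear) " (middle ear included)" else ""))
  invisible(x)
}

# Row index of a level in the response grid.
level_index <- function(fr, level) {
  i <- match(level, fr$levels)
  if (is.na(i)) stop(sprintf("level %g dB SPL not on the response grid", level))
  i
}

# Peak frequency (grid argmax) at one level.
peak_frequency <- function(fr, level) {
  fr$freqs[which.max(fr$magnitude[level_index(fr, level), ])]
}

#' Add a measurement noise floor to a synthetic response
#'
#' Adds complex Gaussian measurement noise of RMS magnitude `noise_nm` to
#' every (level, frequency) cell, emulating the displacement noise floor of
#' real recordings. The generator itself is deterministic; this operation is
#' the only stochastic element and requires an explicit seed.
#'
#' @param fr A `frequency_response`.
#' @param noise_nm RMS magnitude of the complex noise, nm.
#' @param seed Integer seed (required, for reproducibility).
#' @return The `frequency_response` with perturbed magnitudes and phases.
#' @export
add_noise_floor <- function(fr, noise_nm = 0.003, seed) {
  stopifnot(inherits(fr, "frequency_response"))
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  n <- length(fr$magnitude)
  z <- fr$magnitude * exp(2i * pi * fr$phase) +
    complex(real = stats::rnorm(n, sd = noise_nm / sqrt(2)),
            imaginary = stats::rnorm(n, sd = noise_nm / sqrt(2)))
  dim(z) <- dim(fr$magnitude)
  # keep unwrapped-phase continuity: apply the wrapped phase perturbation
  dphi <- wrap_cycles(Arg(z) / (2 * pi) - wrap_cycles(fr$phase))
  fr$magnitude <- Mod(z)
  fr$phase <- fr$phase + dphi
  fr
}

#' Calibration report for a synthetic frequency response
#'
#' Summarises the statistical structure the generator is required to emulate:
#' nonlinear gain between 30 and 90 dB SPL, Q10dB at each level and the
#' 40/75 dB SPL Q10dB ratio, the downward peak shift across level, and the
#' phase at CF (middle-ear contribution excluded).
#'
#' @param fr A `frequency_response` containing at least levels 30, 40, 75 and
#'   90 dB SPL.
#' @return A list of class `calibration_metrics` with elements `gain_db`,
#'   `q10_by_level` (named vector), `q10_ratio_40_75`, `peak_shift_octaves`
#'   and `phase_at_cf` (cycles).
#' @export
calibration_report <- function(fr) {
  stopifnot(inherits(fr, "frequency_response"))
  need <- c(30, 40, 75, 90)
  if (!all(need %in% fr$levels)) {
    stop("calibration requires levels 30, 40, 75 and 90 dB SPL")
  }
  gain_db <- nonlinear_gain(fr)
  q10s <- vapply(fr$levels, function(l) {
    r <- q10(fr$freqs, fr$magnitude[level_index(fr, l), ])
    if (r$defined) r$q10 else NA_real_
  }, numeric(1))
  names(q10s) <- fr$levels
  ratio <- q10s[["40"]] / q10s[["75"]]
  if (!is.finite(ratio)) ratio <- 1  # degenerate flat (passive) responses
  shift <- log2(peak_frequency(fr, min(fr$levels)) /
                  peak_frequency(fr, max(fr$levels)))
  icf <- which.min(abs(fr$freqs - fr$site$cf_ref))
  ph <- fr$phase[level_index(fr, min(fr$levels)), icf]
  if (fr$includes_middle_ear) {
    ph <- ph + fr$freqs[icf] * fr$site$middle_ear_delay
  }
  structure(
    list(gain_db = gain_db, q10_by_level = q10s,
         q10_ratio_40_75 = unname(ratio),
         peak_shift_octaves = shift, phase_at_cf = ph),
    class = "calibration_metrics"
  )
}

#' @export
print.calibration_metrics <- function(x, ...) {
  cat("<calibration_metrics>\n")
  cat(sprintf("  nonlinear gain: %.2f dB\n", x$gain_db))
  cat(sprintf("  Q10dB(40)/Q10dB(75): %.2f\n", x$q10_ratio_40_75))
  cat(sprintf("  peak shift: %.3f oct | phase at CF: %.3f cyc\n",
              x$peak_shift_octaves, x$phase_at_cf))
  invisible(x)
}

#' Write / read a frequency response as a delimited table
#'
#' The on-disk form is a CSV with columns `freq_hz`, `level_db_spl`,
#' `mag_nm_rms`, `phase_cycles`, one row per (level, frequency) pair, written
#' with full double precision so a round trip preserves the grids bit-exactly.
#' Site metadata are stored in `# key: value` header comments.
#'
#' @param fr A `frequency_response`.
#' @param path File path.
#' @return `write_response_table` returns `path` invisibly;
#'   `read_response_table` returns a `frequency_response`.
#' @export
write_response_table <- function(fr, path) {
  stopifnot(inherits(fr, "frequency_response"))
  grid <- expand.grid(freq_hz = fr$freqs, level_db_spl = fr$levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$level_db_spl, grid$freq_hz), ]
  tab <- data.frame(
    freq_hz = grid$freq_hz,
    level_db_spl = grid$level_db_spl,
    mag_nm_rms = as.vector(t(fr$magnitude)),
    phase_cycles = as.vector(t(fr$phase))
  )
  s <- fr$site
  hdr <- c(
    sprintf("# cf_ref: %.17g", s$cf_ref),
    sprintf("# gain_max: %.17g", s$gain_max),
    sprintf("# q_sharpness: %.17g", s$q_sharpness),
    sprintf("# phase_cycles_at_cf: %.17g", s$phase_cycles_at_cf),
    sprintf("# peak_shift_octaves: %.17g", s$peak_shift_octaves),
    sprintf("# middle_ear_delay: %.17g", s$middle_ear_delay),
    sprintf("# cf_mag_30_nm: %.17g", s$cf_mag_30_nm),
    sprintf("# structure_tag: %s", s$structure_tag),
    sprintf("# includes_middle_ear: %s", fr$includes_middle_ear)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  body <- apply(tab, 1, function(r) {
    paste(c(sprintf("%.17g", as.numeric(r[1:4]))), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  tab <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                      collapse = "\n"),
                         colClasses = "numeric")
  need <- c("freq_hz", "level_db_spl", "mag_nm_rms", "phase_cycles")
  if (!all(need %in% colnames(tab))) {
    stop("response table is missing required columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab[, c("freq_hz", "level_db_spl")])) {
    stop("response table contains duplicated (freq, level) rows")
  }
  freqs <- sort(unique(tab$freq_hz))
  levels <- sort(unique(tab$level_db_spl))
  if (nrow(tab) != length(freqs) * length(levels)) {
    stop("response table grid is not rectangular")
  }
  tab <- tab[order(tab$level_db_spl, tab$freq_hz), ]
  magnitude <- matrix(tab$mag_nm_rms, nrow = length(levels),
                      ncol = length(freqs), byrow = TRUE)
  phase <- matrix(tab$phase_cycles, nrow = length(levels),
                  ncol = length(freqs), byrow = TRUE)
  num <- function(k, d) if (is.null(meta[[k]])) d else as.numeric(meta[[k]])
  profile <- site_profile(
    cf_ref = num("cf_ref", 9000),
    gain_max = num("gain_max", 41.1),
    q_sharpness = num("q_sharpness", 1),
    phase_cycles_at_cf = num("phase_cycles_at_cf", 1.5),
    peak_shift_octaves = num("peak_shift_octaves", 0.15),
    middle_ear_delay = num("middle_ear_delay", 36e-6),
    cf_mag_30_nm = num("cf_mag_30_nm", 1.24),
    structure_tag = if (is.null(meta$structure_tag)) "BM" else meta$structure_tag
  )
  structure(
    list(site = profile, freqs = freqs, levels = levels,
         magnitude = magnitude, phase = phase,
         includes_middle_ear = identical(meta$includes_middle_ear, "TRUE")),
    class = "frequency_response"
  )
}
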