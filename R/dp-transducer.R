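# Per-location 2f1-f2 distortion-product generation: two-tone drive of the
# first-order Boltzmann mechanotransduction function, membrane low-pass
# filtering, and extraction of the DP component.

#' Boltzmann mechanotransduction parameters
#'
#' Parameters of the first-order Boltzmann function
#' `y(x) = 1 / (1 + exp(a1 * (x1 - x)))` relating stereociliary bundle
#' displacement (nm) to normalized transduction current.
#'
#' @param a1 Slope parameter in 1/nm.
#' @param x1 Bundle position of maximum slope in nm.
#' @return An object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(a1 = 0.28, x1 = 2.6) {
  if (a1 <= 0) stop("a1 must be positive")
  structure(list(a1 = a1, x1 = x1), class = "boltzmann_params")
}

#' Membrane low-pass filter parameters
#'
#' Single-pole low-pass applied to the transducer output, with corner
#' frequency a fixed number of octaves below the local CF.
#'
#' @param octaves_below_cf Corner frequency offset in octaves below CF.
#' @param enabled If `FALSE` the filter is the identity.
#' @return An object of class `lowpass_params`.
#' @export
lowpass_params <- function(octaves_below_cf = 2.36, enabled = TRUE) {
  structure(list(octaves_below_cf = octaves_below_cf, enabled = isTRUE(enabled)),
            class = "lowpass_params")
}

#' First-order Boltzmann transducer function
#'
#' @param x Bundle displacement(s) in nm.
#' @param p A [boltzmann_params()].
#' @return Normalized transduction current in (0, 1).
#' @export
boltzmann <- function(x, p = boltzmann_params()) {
  1 / (1 + exp(p$a1 * (p$x1 - x)))
}

# Analytic third derivative of the Boltzmann function at the operating point,
# used for small-signal cubic-distortion checks:
# y''' = a1^3 y (1 - y) (1 - 6 y + 6 y^2).
boltzmann_d3 <- function(x, p = boltzmann_params()) {
  y <- boltzmann(x, p)
  p$a1^3 * y * (1 - y) * (1 - 6 * y + 6 * y^2)
}

#' Two-tone drive of one cochlear location
#'
#' @param f1,f2 Primary frequencies in Hz with `f2 > f1 > 0`.
#' @param amp1,amp2 Peak displacement amplitudes of the sinusoidal drives, nm.
#' @param phase1,phase2 Drive phases in cycles (local displacement response
#'   phases; lags negative).
#' @return An object of class `two_tone_drive` with the derived `f_dp = 2 f1 - f2`.
#' @export
two_tone_drive <- function(f1, f2, amp1, amp2, phase1 = 0, phase2 = 0) {
  if (!(f2 > f1) || f1 <= 0) stop("need f2 > f1 > 0")
  f_dp <- 2 * f1 - f2
  if (f_dp <= 0) stop("2 f1 - f2 must be positive (f2/f1 ratio < 2)")
  structure(list(f1 = f1, f2 = f2, amp1 = amp1, amp2 = amp2,
                 phase1 = phase1, phase2 = phase2, f_dp = f_dp),
            class = "two_tone_drive")
}

# Check that a frequency completes an integer number of cycles in `duration`.
is_commensurate <- function(f, duration, tol = 1e-6) {
  abs(f * duration - round(f * duration)) < tol
}

#' Simulate the 2f1-f2 distortion product of a Boltzmann transducer
#'
#' Drives the Boltzmann function with the sum of two sinusoids over a
#' steady-state analysis window containing an integer number of cycles of
#' both primaries, and extracts the complex amplitude of the `2 f1 - f2`
#' component by projection onto the corresponding Fourier bin. Amplitudes are
#' peak values; the returned complex value is the peak amplitude of the DP
#' cosine component, whose phase (in small-signal conditions) follows
#' `2 phase1 - phase2 + c` with `c = 0.5` cycles when the local cubic
#' coefficient of the nonlinearity is negative.
#'
#' @param drive A [two_tone_drive()].
#' @param p A [boltzmann_params()].
#' @param fs Sampling rate in Hz; must be at least `20 * f2`.
#' @param duration Window length in s; `f1`, `f2` (and hence `f_dp`) must be
#'   integer multiples of `1/duration`. The defaults (100 ms window) pair
#'   with stimulus frequencies rounded to the nearest 10 Hz.
#' @return Complex peak amplitude of the DP component (normalized transducer
#'   units).
#' @export
simulate_two_tone_dp <- function(drive, p = boltzmann_params(),
                                 fs = 4e5, duration = 0.1) {
  stopifnot(inherits(drive, "two_tone_drive"))
  if (!is_commensurate(drive$f1, duration) ||
      !is_commensurate(drive$f2, duration)) {
    stop("f1 and f2 must complete an integer number of cycles in the window; ",
         "round them (e.g. with round_frequency()) or adjust duration")
  }
  if (fs < 20 * drive$f2) {
    stop(sprintf("fs = %g Hz is too low for f2 = %g Hz (need fs >= 20 f2)",
                 fs, drive$f2))
  }
  n <- as.integer(round(fs * duration))
  out <- .dp_kernel(drive$amp1, drive$phase1, drive$amp2, drive$phase2,
                    drive$f1, drive$f2, drive$f_dp, fs, n, p$a1, p$x1)
  out[1]
}

# Pure-R reference implementation of the same computation (independent of the
# compiled kernel); used in tests as a cross-check.
simulate_two_tone_dp_r <- function(drive, p = boltzmann_params(),
                                   fs = 4e5, duration = 0.1) {
  n <- as.integer(round(fs * duration))
  t <- (seq_len(n) - 1) / fs
  x <- drive$amp1 * cos(2 * pi * (drive$f1 * t + drive$phase1)) +
    drive$amp2 * cos(2 * pi * (drive$f2 * t + drive$phase2))
  y <- boltzmann(x, p)
  sum(y * exp(-2i * pi * drive$f_dp * t)) * 2 / n
}

#' Membrane low-pass transfer function
#'
#' Single-pole response `H(f) = 1 / (1 + i f / fc)` with corner
#' `fc = cf * 2^(-octaves_below_cf)`; identity when the filter is disabled.
#'
#' @param f Frequency/frequencies in Hz.
#' @param cf Local characteristic frequency in Hz.
#' @param lp A [lowpass_params()].
#' @return Complex transfer value(s) with `|H| <= 1` and phase lag in
#'   `(-0.25, 0]` cycles.
#' @export
lowpass_transfer <- function(f, cf, lp = lowpass_params()) {
  if (any(f <= 0) || any(cf <= 0)) stop("f and cf must be positive")
  if (!lp$enabled) return(rep(1 + 0i, max(length(f), length(cf))))
  fc <- cf * 2^(-lp$octaves_below_cf)
  1 / (1 + 1i * f / fc)
}

#' Locally generated distortion products along the cochlea
#'
#' At each position of two co-registered spatial fields (the traveling-wave
#' profiles at `f1` and `f2`), drives the Boltzmann transducer with the local
#' displacements (RMS magnitudes converted to peak via sqrt(2)), extracts the
#' `2 f1 - f2` component, and applies the membrane low-pass at the local CF.
#'
#' @param field1,field2 `spatial_field`s at `f1` and `f2` sharing a position
#'   grid.
#' @param map A [place_map()].
#' @param p A [boltzmann_params()].
#' @param lp A [lowpass_params()].
#' @param fs,duration Simulation parameters, see [simulate_two_tone_dp()].
#' @return A data frame of class `local_dp_set` with columns `pos_mm`,
#'   `f_dp`, `dp_generated` (complex, normalized units) and `dp_stapes`
#'   (complex; `NA` until [propagate_to_stapes()] is applied).
#' @export
local_dp <- function(field1, field2, map, p = boltzmann_params(),
                     lp = lowpass_params(), fs = 4e5, duration = 0.1) {
  stopifnot(inherits(field1, "spatial_field"), inherits(field2, "spatial_field"))
  if (length(field1$pos_mm) != length(field2$pos_mm) ||
      any(field1$pos_mm != field2$pos_mm)) {
    stop("field1 and field2 must share the position grid")
  }
  f1 <- field1$stim_freq
  f2 <- field2$stim_freq
  if (!(f2 > f1)) stop("field1 must carry the lower primary (f1 < f2)")
  f_dp <- 2 * f1 - f2
  if (f_dp <= 0) stop("2 f1 - f2 must be positive")
  if (!is_commensurate(f1, duration) || !is_commensurate(f2, duration)) {
    stop("primary frequencies are not commensurate with the analysis window")
  }
  if (fs < 20 * f2) stop("fs too low (need fs >= 20 f2)")

  n <- as.integer(round(fs * duration))
  dp_raw <- .dp_kernel(sqrt(2) * field1$mag_nm, field1$phase_cycles,
                       sqrt(2) * field2$mag_nm, field2$phase_cycles,
                       f1, f2, f_dp, fs, n, p$a1, p$x1)
  h <- lowpass_transfer(f_dp, cf_at(map, field1$pos_mm), lp)
  out <- data.frame(pos_mm = field1$pos_mm, f_dp = f_dp)
  out$dp_generated <- dp_raw * h
  out$dp_stapes <- complex(real = NA_real_, imaginary = NA_real_)
  class(out) <- c("local_dp_set", "data.frame")
  out
}
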