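# Measurement-convention utilities: steady-state component extraction, noise
# floors, DP phase referencing, stimulus-frequency rounding, middle-ear delay
# removal.

#' Extract a steady-state spectral component from a waveform
#'
#' Projects the waveform onto the complex exponential at `f` over a window
#' containing an integer number of cycles, returning the RMS magnitude and
#' phase (in cycles) of that component. Orthogonality of Fourier bins makes
#' the extraction exact for commensurate tones.
#'
#' @param waveform Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param f Component frequency in Hz; `f * length(waveform) / fs` must be an
#'   integer (integer number of cycles in the window).
#' @return List with `magnitude` (RMS), `phase` (cycles, in (-0.5, 0.5\]) and
#'   the complex RMS amplitude `value`.
#' @export
extract_component <- function(waveform, fs, f) {
  n <- length(waveform)
  if (n < 2) stop("waveform too short")
  cycles <- f * n / fs
  if (abs(cycles - round(cycles)) > 1e-6) {
    stop(sprintf("f = %g Hz does not complete an integer number of cycles in the window", f))
  }
  t <- (seq_len(n) - 1) / fs
  a <- sum(waveform * exp(-2i * pi * f * t)) * 2 / n  # peak complex amplitude
  value <- a / sqrt(2)
  list(magnitude = Mod(value), phase = wrap_cycles(Arg(a) / (2 * pi)),
       value = value)
}

#' Spectrum record
#'
#' Container for a one-sided magnitude/phase spectrum on a uniform bin grid.
#'
#' @param freqs Ascending, uniformly spaced bin frequencies in Hz.
#' @param magnitudes RMS magnitudes per bin.
#' @param phases Phases in cycles per bin.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(freqs, magnitudes, phases = rep(0, length(freqs))) {
  stopifnot(length(freqs) == length(magnitudes),
            length(freqs) == length(phases))
  if (is.unsorted(freqs, strictly = TRUE)) stop("bins must be ascending")
  dv <- diff(freqs)
  if (length(dv) && max(abs(dv - dv[1])) > 1e-9 * dv[1]) {
    stop("bins must be uniformly spaced")
  }
  structure(list(freqs = freqs, magnitudes = magnitudes, phases = phases,
                 bin_width = if (length(dv)) dv[1] else NA_real_),
            class = "spectrum_record")
}

#' Noise floor around a spectral component
#'
#' Mean + 3 sample standard deviations of the magnitudes in the bins whose
#' offset from `f` lies within `band` on either side (the component bin
#' itself is excluded by construction since `band[1] > 0`). Default bands:
#' 20-120 Hz for DP components, 220-320 Hz for stimulus components.
#'
#' @param spec A [spectrum_record()].
#' @param f Component frequency in Hz.
#' @param band Two-element interval of absolute offsets in Hz, e.g.
#'   `c(20, 120)`.
#' @return Noise-floor magnitude.
#' @export
noise_floor <- function(spec, f, band = c(20, 120)) {
  stopifnot(inherits(spec, "spectrum_record"), length(band) == 2)
  if (band[1] <= 0) stop("band must exclude the component bin (lower edge > 0)")
  off <- abs(spec$freqs - f)
  sel <- off >= band[1] & off <= band[2]
  if (sum(sel) < 2) stop("fewer than 2 neighbor bins in the band")
  m <- spec$magnitudes[sel]
  mean(m) + 3 * stats::sd(m)
}

#' Reference a DP phase to the ear-canal primaries
#'
#' Subtracts `2 phi1ec - phi2ec` from the measured DP phase and wraps the
#' result to (-0.5, 0.5] cycles (unwrapping across a sweep, when needed, is
#' done afterwards in order of increasing DP frequency).
#'
#' @param phi_dp DP response phase in cycles.
#' @param phi1ec,phi2ec Ear-canal phases of the f1 and f2 stimuli in cycles.
#' @return Referenced phase in cycles, wrapped to (-0.5, 0.5].
#' @export
reference_dp_phase <- function(phi_dp, phi1ec, phi2ec) {
  wrap_cycles(phi_dp - (2 * phi1ec - phi2ec))
}

#' Round a stimulus frequency to the nearest 10 Hz
#'
#' Half-up on ties, so an exact multiple of 5 Hz rounds away from zero.
#'
#' @param f Frequency/frequencies in Hz, positive.
#' @return Rounded frequency in Hz.
#' @export
round_frequency <- function(f) {
  if (any(f <= 0)) stop("frequencies must be positive")
  floor(f / 10 + 0.5) * 10
}

#' Remove the forward middle-ear delay from a frequency response
#'
#' Adds `f * tau` cycles to every phase (removing a pure delay of `tau`
#' seconds) and clears the `includes_middle_ear` flag, so that the remaining
#' phases reflect traveling-wave propagation only. Magnitudes are unchanged.
#'
#' @param fr A `frequency_response` with `includes_middle_ear` set.
#' @param tau Delay in seconds; defaults to the profile's `middle_ear_delay`.
#' @return The corrected `frequency_response`.
#' @export
remove_middle_ear_delay <- function(fr, tau = fr$site$middle_ear_delay) {
  stopifnot(inherits(fr, "frequency_response"))
  if (!fr$includes_middle_ear) {
    stop("middle-ear delay has already been removed from this response")
  }
  fr$phase <- fr$phase + outer(rep(1, length(fr$levels)), fr$freqs * tau)
  fr$includes_middle_ear <- FALSE
  fr
}
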