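# Frequency-to-place map of the mouse cochlea and scaling-symmetry
# extrapolation of a single-site frequency response into spatial profiles.

#' Mouse cochlear frequency-to-place map
#'
#' Log-linear map between position along the basilar membrane (in % distance
#' from the base) and characteristic frequency:
#' `position(%) = coef_a - coef_b * log10(f / 1 kHz)`.
#'
#' @param length_mm Length of the basilar membrane in mm.
#' @param coef_a Intercept in percent.
#' @param coef_b Slope in percent per decade.
#' @return An object of class `place_map`.
#' @export
place_map <- function(length_mm = 5.13, coef_a = 156.5, coef_b = 82.5) {
  if (length_mm <= 0) stop("length_mm must be positive")
  if (coef_b <= 0) stop("coef_b must be positive for a monotone map")
  structure(list(length_mm = length_mm, coef_a = coef_a, coef_b = coef_b),
            class = "place_map")
}

#' @export
print.place_map <- function(x, ...) {
  cat(sprintf("<place_map> %.2f mm, CF %.3g-%.3g kHz (base to apex)\n",
              x$length_mm, cf_at(x, 0) / 1000, cf_at(x, x$length_mm) / 1000))
  invisible(x)
}

#' Characteristic frequency at a cochlear position
#'
#' @param map A [place_map()].
#' @param x Position(s) in mm from the base, within `[0, length_mm]`.
#' @return CF in Hz (strictly decreasing in `x`).
#' @export
cf_at <- function(map, x) {
  stopifnot(inherits(map, "place_map"))
  if (any(x < 0 | x > map$length_mm)) {
    stop("position outside [0, length_mm]")
  }
  pct <- 100 * x / map$length_mm
  1000 * 10^((map$coef_a - pct) / map$coef_b)
}

#' Cochlear place of a frequency
#'
#' Inverse of [cf_at()]: the position (mm from base) whose CF equals `f`.
#'
#' @param map A [place_map()].
#' @param f Frequency/frequencies in Hz within the map's CF range.
#' @return Position in mm from the base.
#' @export
place_of <- function(map, f) {
  stopifnot(inherits(map, "place_map"))
  lo <- cf_at(map, map$length_mm)
  hi <- cf_at(map, 0)
  if (any(f < lo | f > hi)) {
    stop(sprintf("frequency outside map range [%.1f, %.1f] Hz", lo, hi))
  }
  pct <- map$coef_a - map$coef_b * log10(f / 1000)
  map$length_mm * pct / 100
}

#' Spatial traveling-wave profile from a single-site frequency response
#'
#' Uses cochlear scaling symmetry: the response of the location with CF(x) to
#' a tone at `f` is taken to equal the reference site's response at the
#' equivalent frequency `f' = f * cf_ref / CF(x)`. Magnitude is interpolated
#' in dB and unwrapped phase in cycles, both linearly in log2 frequency, with
#' straight-line extrapolation from the two nearest grid points beyond the
#' reference grid. The reference response must have its middle-ear delay
#' removed so that phases reflect traveling-wave propagation only.
#'
#' @param fr_ref Reference `frequency_response` (middle-ear-free).
#' @param map A [place_map()].
#' @param f Stimulus frequency in Hz.
#' @param level Stimulus level in dB SPL; either on the reference level grid
#'   or bracketed by it (linear interpolation in dB magnitude and cycles).
#' @param positions Position grid in mm from the base (default 0 to
#'   `length_mm` in 0.01 mm steps, inclusive).
#' @return A `spatial_field`: list with `stim_freq`, `stim_level`, `pos_mm`,
#'   `mag_nm` and `phase_cycles` (unwrapped, lags negative).
#' @export
spatial_response <- function(fr_ref, map, f, level,
                             positions = seq(0, map$length_mm, by = 0.01)) {
  stopifnot(inherits(fr_ref, "frequency_response"), inherits(map, "place_map"))
  if (fr_ref$includes_middle_ear) {
    stop("reference response still contains the middle-ear delay; ",
         "apply remove_middle_ear_delay() first")
  }
  if (length(f) != 1 || f <= 0) stop("f must be a single positive frequency")
  if (is.unsorted(positions, strictly = TRUE) ||
      any(positions < 0 | positions > map$length_mm)) {
    stop("positions must be ascending within [0, length_mm]")
  }

  lv <- fr_ref$levels
  if (level %in% lv) {
    mag_db_row <- db(fr_ref$magnitude[match(level, lv), ])
    ph_row <- fr_ref$phase[match(level, lv), ]
  } else {
    if (level < min(lv) || level > max(lv)) {
      stop(sprintf("level %g dB SPL outside the reference level grid", level))
    }
    i <- findInterval(level, lv)
    wgt <- (level - lv[i]) / (lv[i + 1] - lv[i])
    mag_db_row <- (1 - wgt) * db(fr_ref$magnitude[i, ]) +
      wgt * db(fr_ref$magnitude[i + 1, ])
    ph_row <- (1 - wgt) * fr_ref$phase[i, ] + wgt * fr_ref$phase[i + 1, ]
  }

  lf_grid <- log2(fr_ref$freqs)
  f_equiv <- f * fr_ref$site$cf_ref / cf_at(map, positions)
  lf <- log2(f_equiv)
  mag <- undb(interp_extrap(lf_grid, mag_db_row, lf))
  phase <- interp_extrap(lf_grid, ph_row, lf)

  structure(
    list(stim_freq = f, stim_level = level, pos_mm = positions,
         mag_nm = mag, phase_cycles = phase),
    class = "spatial_field"
  )
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("<spatial_field> %.4g kHz at %g dB SPL, %d positions, peak %.3g nm at %.2f mm\n",
              x$stim_freq / 1000, x$stim_level, length(x$pos_mm),
              max(x$mag_nm), x$pos_mm[which.max(x$mag_nm)]))
  invisible(x)
}
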