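# Site profiles describing a cochlear measurement location.

#' Cochlear site profile
#'
#' Bundles the parameters describing the single-tone response of one cochlear
#' location: its characteristic frequency (CF), the amount of compressive
#' nonlinear gain, tuning sharpness, accumulated traveling-wave phase lag, the
#' level-dependent downward peak shift and the forward middle-ear delay.
#' Profiles parameterise [generate_frequency_response()].
#'
#' @param cf_ref Characteristic frequency of the site in Hz.
#' @param gain_max Nonlinear gain in dB: the drop in stimulus-normalized CF
#'   response magnitude between 30 and 90 dB SPL.
#' @param q_sharpness Dimensionless multiplier applied to all bandwidth
#'   parameters (magnitude and phase widths shrink by `1/q_sharpness`).
#'   1 for the apical (9 kHz) site; ~1.5-1.8 for middle-turn (20-23 kHz) sites.
#' @param phase_cycles_at_cf Accumulated traveling-wave phase lag at CF at low
#'   stimulus level, in cycles (stored as a positive number; response phases
#'   are negative, i.e. lags). Published measurements rarely tabulate this
#'   quantity; the default is the total lag produced by the near-CF
#'   transition plus the slow baseline accumulation across the tail.
#' @param peak_shift_octaves Downward shift of the response peak, in octaves,
#'   from the lowest to the highest stimulus level.
#' @param middle_ear_delay Forward middle-ear delay in seconds.
#' @param cf_mag_30_nm CF displacement magnitude (nm RMS) for a 30 dB SPL tone;
#'   sets the absolute scale of the generated magnitudes and hence the drive
#'   into the mechanotransduction nonlinearity.
#' @param structure_tag One of `"BM"`, `"OHC_region"`, `"TM"`.
#'
#' @return An object of class `site_profile`.
#' @seealso [apical_profile()], [middle_turn_profile()]
#' @export
site_profile <- function(cf_ref = 9000,
                         gain_max = 41.1,
                         q_sharpness = 1,
                         phase_cycles_at_cf = 2.45,
                         peak_shift_octaves = 0.15,
                         middle_ear_delay = 36e-6,
                         cf_mag_30_nm = 1.24,
                         structure_tag = c("BM", "OHC_region", "TM")) {
  structure_tag <- match.arg(structure_tag)
  stopifnot(is.numeric(cf_ref), length(cf_ref) == 1, is.finite(cf_ref))
  if (cf_ref <= 0) stop("cf_ref must be positive")
  if (gain_max < 0) stop("gain_max must be >= 0")
  if (q_sharpness <= 0) stop("q_sharpness must be positive")
  if (middle_ear_delay < 0) stop("middle_ear_delay must be >= 0")
  if (cf_mag_30_nm <= 0) stop("cf_mag_30_nm must be positive")
  structure(
    list(
      cf_ref = cf_ref,
      gain_max = gain_max,
      q_sharpness = q_sharpness,
      phase_cycles_at_cf = phase_cycles_at_cf,
      peak_shift_octaves = peak_shift_octaves,
      middle_ear_delay = middle_ear_delay,
      cf_mag_30_nm = cf_mag_30_nm,
      structure_tag = structure_tag
    ),
    class = "site_profile"
  )
}

#' Default apical (CF 9 kHz) basilar-membrane profile
#'
#' @param ... Overrides passed to [site_profile()].
#' @return A `site_profile`.
#' @export
apical_profile <- function(...) {
  site_profile(...)
}

#' Default middle-turn (CF 20 kHz) basilar-membrane profile
#'
#' Middle-turn sites are more sharply tuned (Q10dB ~1.5-1.8x the apical value)
#' with slightly lower nonlinear gain and smaller absolute displacements. The
#' level-dependent peak glide scales with tuning sharpness, so the default
#' peak shift is the apical 0.15 octaves divided by the sharpness multiplier.
#'
#' @param cf_ref Characteristic frequency in Hz (20-23 kHz region).
#' @param q_sharpness Bandwidth-narrowing multiplier relative to the apex.
#' @param ... Further overrides passed to [site_profile()].
#' @return A `site_profile`.
#' @export
middle_turn_profile <- function(cf_ref = 20000, q_sharpness = 1.65, ...) {
  site_profile(cf_ref = cf_ref, gain_max = 40.5, q_sharpness = q_sharpness,
               peak_shift_octaves = 0.15 / q_sharpness,
               cf_mag_30_nm = 0.52, ...)
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile> %s site, CF %.3g kHz\n", x$structure_tag,
              x$cf_ref / 1000))
  cat(sprintf("  gain_max %.1f dB | q_sharpness %.2f | phase at CF -%.2f cyc\n",
              x$gain_max, x$q_sharpness, x$phase_cycles_at_cf))
  cat(sprintf("  peak shift %.2f oct | middle-ear delay %.1f us | CF mag @30 dB %.2f nm\n",
              x$peak_shift_octaves, x$middle_ear_delay * 1e6, x$cf_mag_30_nm))
  invisible(x)
}
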