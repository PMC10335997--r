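# Propagation of locally generated DPs to the stapes, vector summation into a
# DPOAE, and f2/f1 ratio sweeps.

#' Reverse-propagation options for the interference model
#'
#' @param mode `"slow_wave"`: each DP reaching the stapes is weighted by the
#'   local BM displacement that a low-level tone at the DP frequency would
#'   drive, and phase-shifted by the local phase of a forward-traveling BM
#'   wave at the DP frequency (a lag). `"fast_wave"`: DPs reach the stapes
#'   unweighted and unshifted (near-instantaneous fluid propagation).
#' @param weighting `"displacement"` or `"velocity"` (the latter multiplies
#'   the weight by `2 pi f_dp`).
#' @param weight_level Level (dB SPL) of the weighting tone.
#' @param zero_phase_control If `TRUE`, all DP phases are set to 0 before
#'   summation (magnitude sum), removing interference.
#' @param apical_limit_mm If set, DP generation is excluded at locations more
#'   than this distance apical to the f2 place.
#' @return An object of class `propagation_options`.
#' @export
propagation_options <- function(mode = c("slow_wave", "fast_wave"),
                                weighting = c("displacement", "velocity"),
                                weight_level = 40,
                                zero_phase_control = FALSE,
                                apical_limit_mm = NULL) {
  structure(
    list(mode = match.arg(mode), weighting = match.arg(weighting),
         weight_level = weight_level,
         zero_phase_control = isTRUE(zero_phase_control),
         apical_limit_mm = apical_limit_mm),
    class = "propagation_options"
  )
}

#' Propagate locally generated DPs to the stapes
#'
#' In slow-wave mode, multiplies each generated DP by the magnitude of the
#' reverse-propagation weight (the spatial BM response at the DP frequency at
#' `weight_level`) and rotates its phase by the corresponding local
#' traveling-wave phase (a lag, applied as `exp(i 2 pi phi_fw)`). In
#' fast-wave mode `dp_stapes = dp_generated`.
#'
#' @param dps A `local_dp_set` from [local_dp()].
#' @param fr_ref Middle-ear-free reference `frequency_response`.
#' @param map A [place_map()].
#' @param opt A [propagation_options()].
#' @return The `local_dp_set` with `dp_stapes` populated.
#' @export
propagate_to_stapes <- function(dps, fr_ref, map, opt = propagation_options()) {
  stopifnot(inherits(dps, "local_dp_set"))
  if (nrow(dps) == 0) stop("empty local DP set")
  if (opt$mode == "fast_wave") {
    dps$dp_stapes <- dps$dp_generated
    return(dps)
  }
  f_dp <- dps$f_dp[1]
  wfield <- spatial_response(fr_ref, map, f_dp, opt$weight_level,
                             positions = dps$pos_mm)
  w <- wfield$mag_nm
  if (opt$weighting == "velocity") w <- w * 2 * pi * f_dp
  dps$dp_stapes <- dps$dp_generated * w *
    exp(2i * pi * wfield$phase_cycles)
  # unwrapped stapes-bound phase: local DP phase (unwrapped along position)
  # plus the already-smooth reverse-travel lag
  dps$dp_stapes_phase <- unwrap_cycles(Arg(dps$dp_generated) / (2 * pi)) +
    wfield$phase_cycles
  dps
}

#' Vector-sum DPs arriving at the stapes into a DPOAE estimate
#'
#' @param dps A `local_dp_set` with `dp_stapes` populated.
#' @param opt A [propagation_options()]; with `zero_phase_control` the
#'   magnitudes are summed instead (all phases set to 0).
#' @return Complex DPOAE amplitude (arbitrary units).
#' @export
sum_dpoae <- function(dps, opt = propagation_options()) {
  stopifnot(inherits(dps, "local_dp_set"))
  if (nrow(dps) == 0) stop("empty local DP set")
  if (opt$zero_phase_control) {
    return(complex(real = sum(Mod(dps$dp_stapes)), imaginary = 0))
  }
  sum(dps$dp_stapes)
}

#' Spatial phase spread of stapes-bound DPs over the generation region
#'
#' The generation region is the contiguous run of positions around the
#' location of maximum `|dp_generated|` whose magnitude lies within
#' `within_db` of that maximum. The spread is max minus min of the unwrapped
#' `dp_stapes` phase over that region, in cycles.
#'
#' @param dps A `local_dp_set` with `dp_stapes` populated.
#' @param within_db Magnitude criterion defining the generation region (dB).
#' @return Non-negative phase spread in cycles.
#' @export
phase_spread <- function(dps, within_db = 10) {
  stopifnot(inherits(dps, "local_dp_set"))
  mag <- Mod(dps$dp_generated)
  if (all(mag == 0)) stop("all DP magnitudes are zero")
  i_max <- which.max(mag)
  keep <- db(mag) >= db(mag[i_max]) - within_db
  # contiguous run containing the argmax
  lo <- i_max
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i_max
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  ph <- if (!is.null(dps$dp_stapes_phase)) {
    dps$dp_stapes_phase[lo:hi]
  } else {
    unwrap_cycles(Arg(dps$dp_stapes[lo:hi]) / (2 * pi))
  }
  max(ph) - min(ph)
}

#' Modeled DPOAE ratio function
#'
#' Sweeps the f2/f1 ratio at fixed `f2`: for each requested ratio, `f1` is
#' rounded to the nearest 10 Hz (so the stored ratios are the effective
#' `f2/f1` values), traveling-wave profiles at `(f1, level1)` and
#' `(f2, level2)` are built by scaling symmetry, local DPs are generated,
#' propagated to the stapes and vector-summed.
#'
#' @param fr_ref Middle-ear-free reference `frequency_response`.
#' @param map A [place_map()].
#' @param f2 Fixed higher primary frequency in Hz.
#' @param ratios Requested f2/f1 ratios, ascending within \[1.02, 1.87\].
#' @param level1,level2 Levels (dB SPL) of the f1 and f2 tones.
#' @param p A [boltzmann_params()].
#' @param lp A [lowpass_params()].
#' @param opt A [propagation_options()].
#' @param positions Position grid (mm); default 0.01 mm steps over the map.
#' @return A `ratio_function`: list with `f2`, `level1`, `level2`, `ratios`
#'   (effective), `f1`, `f_dp`, `dpoae` (complex), `spread_cycles` (per-ratio
#'   generation-region phase spread) and the options used.
#' @export
ratio_function <- function(fr_ref, map, f2 = 9000,
                           ratios = seq(1.02, 1.87, by = 0.025),
                           level1 = 50, level2 = level1,
                           p = boltzmann_params(), lp = lowpass_params(),
                           opt = propagation_options(),
                           positions = seq(0, map$length_mm, by = 0.01)) {
  ratio_functions(fr_ref, map, f2, ratios, level1, level2, p, lp,
                  opts = list(opt), positions = positions)[[1]]
}

#' Ratio functions for several propagation variants in one sweep
#'
#' Computes the expensive per-location DP generation once per ratio and then
#' applies each propagation variant, returning one `ratio_function` per
#' element of `opts`.
#'
#' @inheritParams ratio_function
#' @param opts List of [propagation_options()].
#' @return List of `ratio_function` objects, one per variant.
#' @export
ratio_functions <- function(fr_ref, map, f2 = 9000,
                            ratios = seq(1.02, 1.87, by = 0.025),
                            level1 = 50, level2 = level1,
                            p = boltzmann_params(), lp = lowpass_params(),
                            opts = list(propagation_options()),
                            positions = seq(0, map$length_mm, by = 0.01)) {
  if (any(ratios < 1.02 - 1e-9 | ratios > 1.87 + 1e-9)) {
    stop("ratios must lie within [1.02, 1.87]")
  }
  if (is.unsorted(ratios, strictly = TRUE)) stop("ratios must be ascending")
  f2 <- round_frequency(f2)
  nr <- length(ratios)
  nv <- length(opts)
  f1s <- vapply(ratios, function(r) round_frequency(f2 / r), numeric(1))
  eff_ratios <- f2 / f1s
  f_dps <- 2 * f1s - f2
  dpoae <- matrix(complex(real = NA_real_, imaginary = NA_real_), nr, nv)
  spread <- matrix(NA_real_, nr, nv)

  f2_field <- spatial_response(fr_ref, map, f2, level2, positions)
  x2_place <- place_of(map, min(max(f2, cf_at(map, map$length_mm)),
                                cf_at(map, 0)))

  for (i in seq_len(nr)) {
    f1_field <- spatial_response(fr_ref, map, f1s[i], level1, positions)
    dps <- local_dp(f1_field, f2_field, map, p, lp)
    for (v in seq_len(nv)) {
      opt <- opts[[v]]
      d <- dps
      if (!is.null(opt$apical_limit_mm)) {
        cut <- d$pos_mm > x2_place + opt$apical_limit_mm
        d$dp_generated[cut] <- 0 + 0i
      }
      d <- propagate_to_stapes(d, fr_ref, map, opt)
      dpoae[i, v] <- sum_dpoae(d, opt)
      spread[i, v] <- phase_spread(d)
    }
  }

  lapply(seq_len(nv), function(v) {
    structure(
      list(f2 = f2, level1 = level1, level2 = level2,
           ratios = eff_ratios, f1 = f1s, f_dp = f_dps,
           dpoae = dpoae[, v], spread_cycles = spread[, v],
           options = opts[[v]]),
      class = "ratio_function"
    )
  })
}

#' @export
print.ratio_function <- function(x, ...) {
  i <- which.max(Mod(x$dpoae))
  cat(sprintf("<ratio_function> f2 %.3g kHz, L1/L2 %g/%g dB SPL, %s%s\n",
              x$f2 / 1000, x$level1, x$level2, x$options$mode,
              if (x$options$zero_phase_control) " (zero-phase control)" else ""))
  cat(sprintf("  %d ratios in [%.3f, %.3f]; peak at ratio %.3f (f_dp %.3g kHz)\n",
              length(x$ratios), min(x$ratios), max(x$ratios),
              x$ratios[i], x$f_dp[i] / 1000))
  invisible(x)
}

#' Amplitudes in dB re the sweep maximum
#'
#' @param rf A `ratio_function`.
#' @return Numeric vector of dB values (0 at the peak).
#' @export
dpoae_db_re_max <- function(rf) {
  a <- Mod(rf$dpoae)
  db(a / max(a))
}

#' Locally generated DP amplitude at the f2 place, per ratio
#'
#' Evaluates `|dp_generated|` at the position of the f2 response peak for
#' each f2/f1 ratio (no propagation or summation), the quantity that grows
#' monotonically as f1 approaches f2 while the DPOAE itself is bandpass.
#'
#' @inheritParams ratio_function
#' @param level Common level (dB SPL) of both primaries.
#' @return Data frame with columns `ratio`, `f1`, `f_dp`, `pos_mm`, `amp`.
#' @export
local_dp_ratio_function <- function(fr_ref, map, f2 = 9000,
                                    ratios = seq(1.02, 1.87, by = 0.025),
                                    level = 50,
                                    p = boltzmann_params(),
                                    lp = lowpass_params(),
                                    positions = seq(0, map$length_mm, by = 0.01)) {
  if (any(ratios < 1.02 - 1e-9 | ratios > 1.87 + 1e-9)) {
    stop("ratios must lie within [1.02, 1.87]")
  }
  f2 <- round_frequency(f2)
  f2_field <- spatial_response(fr_ref, map, f2, level, positions)
  i2 <- which.max(f2_field$mag_nm)
  rows <- lapply(ratios, function(r) {
    f1 <- round_frequency(f2 / r)
    f1_field <- spatial_response(fr_ref, map, f1, level, positions)
    dps <- local_dp(f1_field, f2_field, map, p, lp)
    data.frame(ratio = f2 / f1, f1 = f1, f_dp = 2 * f1 - f2,
               pos_mm = dps$pos_mm[i2], amp = Mod(dps$dp_generated[i2]))
  })
  do.call(rbind, rows)
}
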