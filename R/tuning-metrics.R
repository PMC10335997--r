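# Tuning-sharpness metrics: Q10dB, equivalent rectangular bandwidth (ERB)
# and QERB, optimal f2/f1 ratio, nonlinear gain.

new_tuning_result <- function(f_max = NA_real_, bw10 = NA_real_,
                              q10 = NA_real_, erb = NA_real_,
                              q_erb = NA_real_, defined = FALSE,
                              optimal_ratio = NA_real_) {
  structure(list(f_max = f_max, bw10 = bw10, q10 = q10, erb = erb,
                 q_erb = q_erb, defined = defined,
                 optimal_ratio = optimal_ratio),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result>")
  if (!x$defined) cat(" (undefined: -10 dB bandwidth not bracketed)\n") else {
    cat(sprintf(" f_max %.4g Hz", x$f_max))
    if (is.finite(x$bw10)) cat(sprintf(", Q10dB %.3g", x$q10))
    if (is.finite(x$erb)) cat(sprintf(", QERB %.3g", x$q_erb))
    if (is.finite(x$optimal_ratio)) cat(sprintf(", optimal ratio %.3f", x$optimal_ratio))
    cat("\n")
  }
  invisible(x)
}

# -10 dB crossing by linear interpolation of dB amplitude vs log2 frequency
# (or vs linear frequency when log_axis = FALSE). side = -1 searches below the
# peak, +1 above. Returns NA when the curve never reaches -10 dB on that side.
crossing_10db <- function(freqs, amp_db, i_peak, side, drop_db = 10,
                          log_axis = TRUE) {
  target <- amp_db[i_peak] - drop_db
  idx <- if (side < 0) seq(i_peak, 1) else seq(i_peak, length(freqs))
  below <- which(amp_db[idx] <= target)
  if (length(below) == 0) return(NA_real_)
  j <- below[1]               # first point at/below target moving outward
  i_out <- idx[j]
  i_in <- idx[j - 1]
  x <- if (log_axis) log2(freqs) else freqs
  w <- (target - amp_db[i_in]) / (amp_db[i_out] - amp_db[i_in])
  xc <- x[i_in] + w * (x[i_out] - x[i_in])
  if (log_axis) 2^xc else xc
}

#' Q10dB tuning sharpness of an amplitude curve
#'
#' Peak frequency divided by the bandwidth 10 dB below the peak. Crossings
#' are located by linear interpolation of dB amplitude versus log2 frequency
#' (versus linear frequency with `log_axis = FALSE`). When the curve never
#' falls 10 dB below the peak on one side, the result is flagged undefined
#' rather than extrapolated.
#'
#' @param freqs Ascending frequencies in Hz (>= 3 points).
#' @param amps Linear amplitudes (any units).
#' @param log_axis Interpolate crossings in log2 frequency (default) or
#'   linear frequency.
#' @return A `tuning_result` with `f_max`, `bw10`, `q10` and `defined`.
#' @export
q10 <- function(freqs, amps, log_axis = TRUE) {
  stopifnot(length(freqs) == length(amps), length(freqs) >= 3)
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be ascending")
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  i_peak <- which.max(amps)
  amp_db <- db(amps / amps[i_peak])
  f_lo <- crossing_10db(freqs, amp_db, i_peak, -1, log_axis = log_axis)
  f_hi <- crossing_10db(freqs, amp_db, i_peak, +1, log_axis = log_axis)
  f_max <- freqs[i_peak]
  if (is.na(f_lo) || is.na(f_hi)) {
    return(new_tuning_result(f_max = f_max, defined = FALSE))
  }
  bw <- f_hi - f_lo
  new_tuning_result(f_max = f_max, bw10 = bw, q10 = f_max / bw,
                    defined = TRUE)
}

#' Equivalent-rectangular-bandwidth tuning sharpness
#'
#' Normalizes the amplitudes (linear units) to their maximum, squares them so
#' they are proportional to power, and integrates over linear frequency by
#' the trapezoid rule; the ERB is that area and `QERB = f_max / ERB`.
#' A warning flags curves whose squared normalized amplitude at either grid
#' end exceeds 0.05, where truncation biases the integral.
#'
#' @inheritParams q10
#' @return A `tuning_result` with `f_max`, `erb`, `q_erb` and `defined`.
#' @export
qerb <- function(freqs, amps) {
  stopifnot(length(freqs) == length(amps), length(freqs) >= 3)
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be ascending")
  i_peak <- which.max(amps)
  pw <- (amps / amps[i_peak])^2
  if (pw[1] > 0.05 || pw[length(pw)] > 0.05) {
    warning("amplitude curve does not decay at the grid edges; ERB is biased low")
  }
  erb <- trapz(freqs, pw)
  new_tuning_result(f_max = freqs[i_peak], erb = erb,
                    q_erb = freqs[i_peak] / erb, defined = TRUE)
}

#' Tuning of a modeled DPOAE ratio function
#'
#' Applies [q10()] and [qerb()] to the DPOAE amplitudes as a function of the
#' DP frequency (not of the ratio), and reports the optimal f2/f1 ratio (the
#' ratio maximizing `|dpoae|`; the smallest such ratio on ties).
#'
#' @param rf A `ratio_function`.
#' @param log_axis Passed to [q10()].
#' @return A `tuning_result` with `optimal_ratio` populated.
#' @export
ratio_function_tuning <- function(rf, log_axis = TRUE) {
  stopifnot(inherits(rf, "ratio_function"))
  ord <- order(rf$f_dp)
  freqs <- rf$f_dp[ord]
  amps <- Mod(rf$dpoae)[ord]
  rq <- q10(freqs, amps, log_axis = log_axis)
  re <- qerb(freqs, amps)
  a <- Mod(rf$dpoae)
  i_opt <- which(a == max(a))
  opt <- min(rf$ratios[i_opt])  # smallest ratio wins ties
  new_tuning_result(f_max = rq$f_max, bw10 = rq$bw10, q10 = rq$q10,
                    erb = re$erb, q_erb = re$q_erb, defined = rq$defined,
                    optimal_ratio = opt)
}

#' Nonlinear gain of a frequency response
#'
#' The dB difference between the stimulus-normalized CF responses at 30 and
#' 90 dB SPL. The CF is the site's nominal characteristic frequency (the
#' grid point closest to `cf_ref`); for responses without a meaningful site
#' CF it falls back to the peak frequency at the lowest level. A linear
#' response yields 0 dB.
#'
#' @param fr A `frequency_response` containing levels 30 and 90 dB SPL.
#' @return Gain in dB.
#' @export
nonlinear_gain <- function(fr) {
  stopifnot(inherits(fr, "frequency_response"))
  if (!all(c(30, 90) %in% fr$levels)) {
    stop("nonlinear gain requires responses at 30 and 90 dB SPL")
  }
  icf <- if (!is.null(fr$site$cf_ref)) {
    which.min(abs(fr$freqs - fr$site$cf_ref))
  } else {
    which.max(fr$magnitude[level_index(fr, min(fr$levels)), ])
  }
  m30 <- fr$magnitude[level_index(fr, 30), icf] / spl_to_pa(30)
  m90 <- fr$magnitude[level_index(fr, 90), icf] / spl_to_pa(90)
  db(m30) - db(m90)
}

#' Average tuning results across repeats
#'
#' Arithmetic mean of the tuning metrics across a list of defined
#' `tuning_result`s (undefined members are an error, mirroring the exclusion
#' of conditions where the bandwidth could not be quantified).
#'
#' @param results Nonempty list of `tuning_result`s.
#' @return A `tuning_result` with averaged fields.
#' @export
average_tuning <- function(results) {
  if (length(results) == 0) stop("no tuning results to average")
  ok <- vapply(results, function(r) inherits(r, "tuning_result") && r$defined,
               logical(1))
  if (!all(ok)) stop("cannot average undefined tuning results")
  m <- function(field) mean(vapply(results, function(r) r[[field]], numeric(1)))
  new_tuning_result(f_max = m("f_max"), bw10 = m("bw10"), q10 = m("q10"),
                    erb = m("erb"), q_erb = m("q_erb"), defined = TRUE,
                    optimal_ratio = m("optimal_ratio"))
}
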