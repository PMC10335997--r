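# Small shared numerics helpers.

# Sound pressure (Pa) of a tone at L dB SPL (re 20 uPa).
spl_to_pa <- function(level_db_spl) 20e-6 * 10^(level_db_spl / 20)

db <- function(x) 20 * log10(x)
undb <- function(x) 10^(x / 20)

# Huber-type penalty: quadratic for |u| <= delta, linear beyond. Used for the
# passive magnitude skirt so the near-peak curvature and the far-tail slope
# can be set independently.
huber <- function(u, delta) {
  u <- abs(u)
  ifelse(u <= delta, u^2 / 2, delta * (u - delta / 2))
}

# Wrap phase in cycles to (-0.5, 0.5].
wrap_cycles <- function(phi) {
  w <- phi - round(phi)
  # round() maps .5 to the even side; force the boundary to +0.5
  w[w == -0.5] <- 0.5
  w
}

# Unwrap a phase sequence (cycles): remove jumps > 0.5 cycles between
# consecutive samples.
unwrap_cycles <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  phi - c(0, cumsum(round(d)))
}

# Trapezoidal integral on an arbitrary ascending grid.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Linear interpolation with straight-line extrapolation from the two nearest
# grid points on each side (rule used for magnitude-in-dB and phase-in-cycles
# versus log2 frequency).
interp_extrap <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 2)
  yout <- stats::approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    yout[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    yout[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  yout
}
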