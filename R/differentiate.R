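#' Velocity and acceleration from a 17-sample local polynomial model
#'
#' Eye velocity and acceleration are estimated with a centered least-squares
#' (Savitzky-Golay) local quadratic fit over a 17-sample window: the fitted
#' first derivative gives velocity, the second derivative gives acceleration.
#' The filter is exact for polynomials up to the fit order, so a linear ramp
#' yields its slope to machine precision. The 8 samples at each edge have no
#' full window and are returned as `NA`.
#'
#' @param x Position series in degrees.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param window Window length in samples (odd, default 17).
#' @param order Polynomial order of the local fit (default 2).
#' @return A list with `velocity` (deg/s), `acceleration` (deg/s^2) and
#'   `margin`, the number of undefined edge samples per side.
#' @export
differentiate_17 <- function(x, sample_rate_hz = 1000, window = 17, order = 2) {
  n <- length(x)
  if (window %% 2 != 1 || window < order + 1) {
    stop("`window` must be odd and exceed the polynomial order", call. = FALSE)
  }
  if (n < window) {
    stop(sprintf("trace too short for differentiation: %d samples < window %d",
                 n, window), call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  cf <- savgol_coef(window, order)
  # embed() row i holds x[i+window-1], ..., x[i]; reverse coefficients to get
  # sum_{j=-h..h} c_j * x[center+j]
  em <- stats::embed(x, window)
  interior_v <- drop(em %*% rev(cf$d1)) * sample_rate_hz
  interior_a <- drop(em %*% rev(cf$d2)) * sample_rate_hz^2
  pad <- rep(NA_real_, h)
  list(velocity = c(pad, interior_v, pad),
       acceleration = c(pad, interior_a, pad),
       margin = h)
}

# least-squares derivative coefficients: rows of (M'M)^-1 M' for the monomial
# design on -h..h; d1 = first-derivative weights, d2 = second-derivative
savgol_coef <- function(window, order) {
  h <- (window - 1L) %/% 2L
  i <- seq(-h, h)
  m <- outer(i, 0:order, `^`)
  cmat <- solve(crossprod(m), t(m))
  list(d1 = cmat[2L, ],
       d2 = if (order >= 2) 2 * cmat[3L, ] else rep(0, window))
}

#' Detect saccades from velocity and acceleration criteria
#'
#' A sample is saccade-candidate when its absolute velocity is at least
#' `vel_high` deg/s, or at least `vel_low` deg/s with absolute acceleration of
#' at least `accel` deg/s^2. Maximal candidate runs become events and are kept
#' when the net position change across the run is at least `min_amplitude`
#' degrees. Events whose span intersects an invalid (blink) gap extended by
#' `blink_margin_ms` on each side are flagged `near_blink`.
#'
#' @param velocity,acceleration Series from [differentiate_17()] (deg/s,
#'   deg/s^2).
#' @param x Position series in degrees.
#' @param valid Logical validity mask (FALSE = blink/track loss).
#' @param times_ms Sample times in ms.
#' @param vel_high,vel_low,accel,min_amplitude Detection thresholds.
#' @param blink_margin_ms Margin around invalid gaps for the near-blink flag.
#' @return Data frame with one row per accepted event: `onset_ms`,
#'   `offset_ms`, `amplitude_deg`, `peak_velocity_deg_s`, `near_blink`.
#' @export
detect_saccades <- function(velocity, acceleration, x, valid, times_ms,
                            vel_high = 60, vel_low = 22, accel = 3800,
                            min_amplitude = 1.0, blink_margin_ms = 100) {
  n <- length(x)
  stopifnot(length(velocity) == n, length(acceleration) == n,
            length(valid) == n, length(times_ms) == n)
  av <- abs(velocity)
  aa <- abs(acceleration)
  cand <- valid & !is.na(av) & (av >= vel_high | (av >= vel_low & aa >= accel))
  cand[is.na(cand)] <- FALSE

  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0),
                      peak_velocity_deg_s = numeric(0),
                      near_blink = logical(0))
  if (!any(cand)) return(empty)

  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]

  amp <- x[off_i] - x[on_i]
  keep <- !is.na(amp) & abs(amp) >= min_amplitude
  if (!any(keep)) return(empty)
  on_i <- on_i[keep]; off_i <- off_i[keep]; amp <- amp[keep]

  pk <- mapply(function(a, b) max(av[a:b], na.rm = TRUE), on_i, off_i)

  blinks <- invalid_intervals(valid, times_ms)
  near <- rep(FALSE, length(on_i))
  if (nrow(blinks)) {
    for (j in seq_len(nrow(blinks))) {
      lo <- blinks$start_ms[j] - blink_margin_ms
      hi <- blinks$end_ms[j] + blink_margin_ms
      near <- near | (times_ms[on_i] <= hi & times_ms[off_i] >= lo)
    }
  }
  data.frame(onset_ms = times_ms[on_i], offset_ms = times_ms[off_i],
             amplitude_deg = amp, peak_velocity_deg_s = pk, near_blink = near)
}

# contiguous runs of invalid samples as [start_ms, end_ms] intervals
invalid_intervals <- function(valid, times_ms) {
  if (all(valid)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  }
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_ms = times_ms[starts[r$values]],
             end_ms = times_ms[ends[r$values]])
}
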