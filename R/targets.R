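#' Generate a pursuit target trajectory
#'
#' Builds the horizontal position trace of a smooth-pursuit target, either a
#' sinusoid or a triangular (constant-velocity) wave. Motion starts at the
#' central position (0 deg) and moves rightward first. Defaults reproduce the
#' two standard task geometries: a 0.4 Hz sinusoid over 76.57 s and a 13 deg/s
#' triangular wave over 91.50 s, both with an amplitude of +/- 9.80 deg,
#' sampled at 1000 Hz.
#'
#' @param pattern `"sinusoidal"` or `"triangular"`.
#' @param amplitude_deg Peak horizontal excursion in degrees of visual angle.
#' @param frequency_hz Sinusoid frequency in Hz (sinusoidal pattern only).
#' @param speed_deg_s Constant target speed in deg/s (triangular pattern only).
#' @param duration_s Task duration in seconds. Defaults to 76.57 s
#'   (sinusoidal) or 91.50 s (triangular).
#' @param sample_rate_hz Sampling rate of the generated trace in Hz.
#' @return An object of class `target_trajectory`: a list with the task
#'   parameters plus `times_ms` and `positions` (degrees).
#' @examples
#' tgt <- generate_target("sinusoidal")
#' range(tgt$positions)
#' @export
generate_target <- function(pattern = c("sinusoidal", "triangular"),
                            amplitude_deg = 9.80,
                            frequency_hz = 0.4,
                            speed_deg_s = 13,
                            duration_s = NULL,
                            sample_rate_hz = 1000) {
  pattern <- match.arg(pattern)
  if (is.null(duration_s)) {
    duration_s <- if (pattern == "sinusoidal") 76.57 else 91.50
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  }
  if (amplitude_deg <= 0) stop("`amplitude_deg` must be positive", call. = FALSE)

  n <- floor(duration_s * sample_rate_hz) + 1L
  t_s <- (seq_len(n) - 1L) / sample_rate_hz
  if (pattern == "sinusoidal") {
    if (frequency_hz <= 0) stop("`frequency_hz` must be positive", call. = FALSE)
    pos <- amplitude_deg * sin(2 * pi * frequency_hz * t_s)
  } else {
    if (speed_deg_s <= 0) stop("`speed_deg_s` must be positive", call. = FALSE)
    pos <- triangle_wave(t_s, amplitude_deg, speed_deg_s)
  }
  structure(
    list(pattern = pattern,
         amplitude_deg = amplitude_deg,
         frequency_hz = if (pattern == "sinusoidal") frequency_hz else NA_real_,
         speed_deg_s = if (pattern == "triangular") speed_deg_s else NA_real_,
         duration_s = duration_s,
         sample_rate_hz = sample_rate_hz,
         times_ms = t_s * 1000,
         positions = pos),
    class = "target_trajectory"
  )
}

# triangle wave starting at 0 deg, moving right at +v; period 4A/v
triangle_wave <- function(t_s, amplitude, speed) {
  u <- (t_s * speed) %% (4 * amplitude)
  ifelse(u < amplitude, u,
         ifelse(u < 3 * amplitude, 2 * amplitude - u, u - 4 * amplitude))
}

#' Analytic target velocity
#'
#' Exact derivative of the target trajectory at given times. Used as the
#' denominator of the velocity-gain ratio so the target side of the ratio is
#' never numerically filtered.
#'
#' @param target A [target_trajectory][generate_target] object.
#' @param times_ms Times in ms; defaults to the trajectory's own sample times.
#' @return Velocity in deg/s (at a triangular reversal instant the one-sided
#'   velocity of the incoming ramp is returned).
#' @export
target_velocity <- function(target, times_ms = target$times_ms) {
  t_s <- times_ms / 1000
  if (target$pattern == "sinusoidal") {
    w <- 2 * pi * target$frequency_hz
    target$amplitude_deg * w * cos(w * t_s)
  } else {
    a <- target$amplitude_deg
    u <- (t_s * target$speed_deg_s) %% (4 * a)
    ifelse(u < a | u >= 3 * a, target$speed_deg_s, -target$speed_deg_s)
  }
}

#' @export
print.target_trajectory <- function(x, ...) {
  par_txt <- if (x$pattern == "sinusoidal") {
    sprintf("%.2f Hz", x$frequency_hz)
  } else {
    sprintf("%.1f deg/s", x$speed_deg_s)
  }
  cat(sprintf("<target_trajectory> %s, +/-%.2f deg, %s, %.2f s @ %g Hz (%d samples)\n",
              x$pattern, x$amplitude_deg, par_txt, x$duration_s,
              x$sample_rate_hz, length(x$positions)))
  invisible(x)
}

#' Segment a trajectory into half-cycles
#'
#' Finds the direction-reversal points of the target and returns the
#' reversal-to-reversal segments. Data before the first reversal and after the
#' last reversal are dropped; for the two default task geometries exactly 60
#' half-cycles remain (30 rightward, 30 leftward).
#'
#' @param target A [target_trajectory][generate_target] object.
#' @return A data frame of class `half_cycle_set` with columns `half_cycle`,
#'   `cycle` (pair index of consecutive half-cycles), `start_ms`, `end_ms`
#'   (closed-open interval), and `direction` (`"right"`/`"left"`).
#' @export
segment_half_cycles <- function(target) {
  stopifnot(inherits(target, "target_trajectory"))
  idx <- reversal_indices(target$positions)
  if (length(idx) < 2) {
    stop("trajectory has fewer than 2 direction reversals; cannot segment",
         call. = FALSE)
  }
  n_hc <- length(idx) - 1L
  start <- target$times_ms[idx[-length(idx)]]
  end <- target$times_ms[idx[-1L]]
  dir <- ifelse(target$positions[idx[-1L]] > target$positions[idx[-length(idx)]],
                "right", "left")
  out <- data.frame(
    half_cycle = seq_len(n_hc),
    cycle = (seq_len(n_hc) + 1L) %/% 2L,
    start_ms = start,
    end_ms = end,
    direction = dir,
    stringsAsFactors = FALSE
  )
  class(out) <- c("half_cycle_set", "data.frame")
  out
}

# indices of local extrema found by sign changes of the first difference;
# zero differences (flat samples at a triangular vertex) inherit the prior sign
reversal_indices <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  which(diff(s_f) != 0) + 1L
}

#' Assign half-cycles to test sets
#'
#' Cyclic assignment of full cycles to `k` test sets (the indicators of the
#' latent models). For `k = 2` this is the odd-even split, which guarantees
#' that each set contains both rightward and leftward half-cycles.
#'
#' @param half_cycles A [half_cycle_set][segment_half_cycles].
#' @param k Number of test sets: 2, 3 or 4.
#' @return The half-cycle set with an added integer column `set` in `1..k`.
#' @export
split_test_sets <- function(half_cycles, k = 2) {
  if (!k %in% 2:4) stop("`k` must be 2, 3 or 4", call. = FALSE)
  half_cycles$set <- ((half_cycles$cycle - 1L) %% k) + 1L
  half_cycles
}
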