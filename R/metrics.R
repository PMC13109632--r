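#' Time-weighted velocity gain
#'
#' Velocity gain is the time-weighted average of the sample-wise ratio of eye
#' velocity to analytic target velocity, times 100. Only samples inside the
#' middle `central_frac` of each half-cycle contribute, and only when they lie
#' in a contiguous usable run of at least `min_segment_ms`; blink, saccade and
#' noise samples are excluded via `exclude`. `sd_gain` is the time-weighted
#' intra-individual standard deviation of the same ratio samples.
#'
#' @param trace A [gaze_trace].
#' @param target The matching [target_trajectory][generate_target].
#' @param half_cycles Rows of a [half_cycle_set][segment_half_cycles] to use.
#' @param exclude Logical vector (per sample) of samples to exclude (saccades,
#'   noise); invalid samples and samples with undefined velocity are always
#'   excluded.
#' @param velocity Optional precomputed eye velocity (deg/s); computed with
#'   [differentiate_17()] when `NULL`.
#' @param min_segment_ms Minimum duration of a contributing contiguous run.
#' @param central_frac Central fraction of each half-cycle considered.
#' @return List with `gain_pct`, `sd_gain_pct`, `valid_fraction` (usable time
#'   over total central-window time). All `NA` when no time qualifies.
#' @export
compute_gain <- function(trace, target, half_cycles, exclude = NULL,
                         velocity = NULL, min_segment_ms = 50,
                         central_frac = 0.5) {
  fs <- target$sample_rate_hz
  dt_ms <- 1000 / fs
  if (is.null(velocity)) {
    velocity <- differentiate_17(trace$x, fs)$velocity
  }
  if (is.null(exclude)) exclude <- rep(FALSE, length(trace$x))
  vt <- target_velocity(target, trace$times_ms)
  include <- trace$valid & !exclude & !is.na(velocity)

  min_run <- max(1L, ceiling(min_segment_ms / dt_ms))
  ratios <- numeric(0)
  total_n <- 0L
  used_n <- 0L
  trim <- (1 - central_frac) / 2
  for (j in seq_len(nrow(half_cycles))) {
    dur <- half_cycles$end_ms[j] - half_cycles$start_ms[j]
    c_start <- half_cycles$start_ms[j] + trim * dur
    c_end <- half_cycles$end_ms[j] - trim * dur
    idx <- which(trace$times_ms >= c_start & trace$times_ms < c_end)
    if (!length(idx)) next
    total_n <- total_n + length(idx)
    inc <- include[idx]
    if (!any(inc)) next
    r <- rle(inc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= min_run)) {
      sel <- idx[starts[q]:ends[q]]
      ratios <- c(ratios, velocity[sel] / vt[sel])
      used_n <- used_n + length(sel)
    }
  }
  if (!length(ratios)) {
    return(list(gain_pct = NA_real_, sd_gain_pct = NA_real_,
                valid_fraction = 0))
  }
  m <- mean(ratios)
  list(gain_pct = 100 * m,
       sd_gain_pct = 100 * sqrt(mean((ratios - m)^2)),
       valid_fraction = used_n / total_n)
}

#' Time-weighted root mean square positional error
#'
#' RMSE is the square root of the time-weighted mean squared angular distance
#' between eye and target position across all usable samples within the
#' half-cycles. Blinks, saccades around blinks, and noise are excluded;
#' ordinary catch-up saccades are not. `sd_rmse` is the time-weighted standard
#' deviation of the per-half-cycle RMSE values (weights are each half-cycle's
#' usable time).
#'
#' @inheritParams compute_gain
#' @param exclude Logical per-sample exclusion mask (blinks are always
#'   excluded through the trace's validity mask).
#' @return List with `rmse_deg`, `sd_rmse_deg`, `valid_fraction`.
#' @export
compute_rmse <- function(trace, target, half_cycles, exclude = NULL) {
  if (is.null(exclude)) exclude <- rep(FALSE, length(trace$x))
  include <- trace$valid & !exclude
  err2 <- (trace$x - target_position(target, trace$times_ms))^2

  per_sse <- numeric(0)
  per_n <- integer(0)
  total_n <- 0L
  for (j in seq_len(nrow(half_cycles))) {
    idx <- which(trace$times_ms >= half_cycles$start_ms[j] &
                   trace$times_ms < half_cycles$end_ms[j])
    if (!length(idx)) next
    total_n <- total_n + length(idx)
    sel <- idx[include[idx]]
    if (!length(sel)) next
    per_sse <- c(per_sse, sum(err2[sel]))
    per_n <- c(per_n, length(sel))
  }
  if (!length(per_n)) {
    return(list(rmse_deg = NA_real_, sd_rmse_deg = NA_real_,
                valid_fraction = 0))
  }
  rmse_all <- sqrt(sum(per_sse) / sum(per_n))
  rmse_j <- sqrt(per_sse / per_n)
  w <- per_n / sum(per_n)
  m <- sum(w * rmse_j)
  list(rmse_deg = rmse_all,
       sd_rmse_deg = sqrt(sum(w * (rmse_j - m)^2)),
       valid_fraction = sum(per_n) / total_n)
}

#' Target position at arbitrary times
#' @keywords internal
target_position <- function(target, times_ms) {
  t_s <- times_ms / 1000
  if (target$pattern == "sinusoidal") {
    target$amplitude_deg * sin(2 * pi * target$frequency_hz * t_s)
  } else {
    triangle_wave(t_s, target$amplitude_deg, target$speed_deg_s)
  }
}

#' Saccade frequency
#'
#' Number of accepted saccades per second of usable task time. Saccades
#' flagged `near_blink` are not counted.
#'
#' @param events Data frame from [detect_saccades()].
#' @param valid_duration_s Usable task duration in seconds (time within
#'   half-cycles excluding blinks and noise).
#' @return Saccades per second, or `NA` when `valid_duration_s <= 0`.
#' @export
compute_saccade_frequency <- function(events, valid_duration_s) {
  if (!is.numeric(valid_duration_s) || is.na(valid_duration_s) ||
      valid_duration_s <= 0) {
    return(NA_real_)
  }
  sum(!events$near_blink) / valid_duration_s
}

#' Full metric extraction for one trace
#'
#' Runs the complete signal pipeline on one gaze recording: differentiation,
#' saccade detection, mask construction, and computation of the five
#' dependent variables (velocity gain, SD of gain, RMSE, SD of RMSE, saccade
#' frequency) for the whole occasion and per test set, plus per-half-cycle
#' values for the internal-consistency pipeline.
#'
#' @param trace A [gaze_trace].
#' @param target The matching [target_trajectory][generate_target].
#' @param k Number of test sets (2-4).
#' @param noise Optional data frame of noise intervals (`start_ms`,
#'   `end_ms`).
#' @param vel_high,vel_low,accel,min_amplitude,blink_margin_ms Saccade
#'   detection thresholds, see [detect_saccades()].
#' @param min_segment_ms,central_frac Gain-window parameters, see
#'   [compute_gain()].
#' @return List with `metrics` (tidy data frame: `variable`, `set` (0 = whole
#'   occasion), `value`, `valid_fraction`), `half_cycle_values` (per
#'   half-cycle gain/RMSE/saccade count), and `events` (accepted saccades).
#' @export
trace_metrics <- function(trace, target, k = 2, noise = NULL,
                          vel_high = 60, vel_low = 22, accel = 3800,
                          min_amplitude = 1.0, blink_margin_ms = 100,
                          min_segment_ms = 50, central_frac = 0.5) {
  hc <- split_test_sets(segment_half_cycles(target), k)
  der <- differentiate_17(trace$x, target$sample_rate_hz)
  events <- detect_saccades(der$velocity, der$acceleration, trace$x,
                            trace$valid, trace$times_ms,
                            vel_high = vel_high, vel_low = vel_low,
                            accel = accel, min_amplitude = min_amplitude,
                            blink_margin_ms = blink_margin_ms)
  noise_mask <- mask_from_intervals(trace$times_ms, noise)
  sacc_all <- event_mask(trace$times_ms, events)
  sacc_nb <- event_mask(trace$times_ms, events[events$near_blink, , drop = FALSE])

  excl_gain <- sacc_all | noise_mask
  excl_rmse <- sacc_nb | noise_mask

  dt_s <- 1 / target$sample_rate_hz
  rows <- list()
  for (s in 0:k) {
    sub <- if (s == 0) hc else hc[hc$set == s, , drop = FALSE]
    g <- compute_gain(trace, target, sub, exclude = excl_gain,
                      velocity = der$velocity,
                      min_segment_ms = min_segment_ms,
                      central_frac = central_frac)
    r <- compute_rmse(trace, target, sub, exclude = excl_rmse)
    in_hc <- mask_from_intervals(trace$times_ms,
                                 data.frame(start_ms = sub$start_ms,
                                            end_ms = sub$end_ms))
    usable <- in_hc & trace$valid & !noise_mask
    dur_s <- sum(usable) * dt_s
    ev_in <- events[!events$near_blink &
                      in_set(events$onset_ms, sub), , drop = FALSE]
    freq <- compute_saccade_frequency(ev_in, dur_s)
    frac_t <- if (any(in_hc)) sum(usable) / sum(in_hc) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      variable = c("gain", "sd_gain", "rmse", "sd_rmse", "sacc_freq"),
      set = s,
      value = c(g$gain_pct, g$sd_gain_pct, r$rmse_deg, r$sd_rmse_deg, freq),
      valid_fraction = c(g$valid_fraction, g$valid_fraction,
                         r$valid_fraction, r$valid_fraction, frac_t))
  }
  metrics <- do.call(rbind, rows)

  hcv <- half_cycle_values(trace, target, hc, der$velocity, events,
                           excl_gain, excl_rmse, noise_mask,
                           min_segment_ms, central_frac)
  list(metrics = metrics, half_cycle_values = hcv, events = events)
}

in_set <- function(onset_ms, half_cycles) {
  out <- rep(FALSE, length(onset_ms))
  for (j in seq_len(nrow(half_cycles))) {
    out <- out | (onset_ms >= half_cycles$start_ms[j] &
                    onset_ms < half_cycles$end_ms[j])
  }
  out
}

event_mask <- function(times_ms, events) {
  m <- rep(FALSE, length(times_ms))
  if (is.null(events) || nrow(events) == 0) return(m)
  for (j in seq_len(nrow(events))) {
    m <- m | (times_ms >= events$onset_ms[j] & times_ms <= events$offset_ms[j])
  }
  m
}

# per-half-cycle gain, RMSE and saccade counts for the alpha pipeline
half_cycle_values <- function(trace, target, hc, velocity, events,
                              excl_gain, excl_rmse, noise_mask,
                              min_segment_ms, central_frac) {
  dt_s <- 1 / target$sample_rate_hz
  out <- hc
  out$gain <- NA_real_
  out$rmse <- NA_real_
  out$n_saccades <- 0L
  out$valid_fraction <- 0
  for (j in seq_len(nrow(hc))) {
    one <- hc[j, , drop = FALSE]
    g <- compute_gain(trace, target, one, exclude = excl_gain,
                      velocity = velocity, min_segment_ms = min_segment_ms,
                      central_frac = central_frac)
    r <- compute_rmse(trace, target, one, exclude = excl_rmse)
    out$gain[j] <- g$gain_pct
    out$rmse[j] <- r$rmse_deg
    out$valid_fraction[j] <- r$valid_fraction
    out$n_saccades[j] <- sum(!events$near_blink &
                               events$onset_ms >= one$start_ms &
                               events$onset_ms < one$end_ms)
  }
  out
}

#' Apply the data-quality and outlier exclusion rules
#'
#' First drops cells whose value was computed from less than
#' `min_valid_fraction` of the possible time window; then, per variable
#' column (variable x occasion x set), drops values outside
#' `[Q1 - iqr_mult * IQR, Q3 + iqr_mult * IQR]`. When the IQR of a column is
#' zero, no outliers are removed from it.
#'
#' @param tab Tidy metric table with columns `variable`, `value`,
#'   `valid_fraction`, and any grouping columns in `group_cols`.
#' @param min_valid_fraction Minimum usable-time fraction (default 0.5).
#' @param iqr_mult IQR multiplier for the outlier fence (default 4).
#' @param group_cols Columns defining an outlier-detection group together
#'   with `variable`.
#' @return List with `kept` (surviving rows) and `removed` (dropped rows with
#'   a `reason` column).
#' @export
apply_exclusions <- function(tab, min_valid_fraction = 0.5, iqr_mult = 4,
                             group_cols = intersect(c("occasion", "set", "task"),
                                                    names(tab))) {
  stopifnot(all(c("variable", "value") %in% names(tab)))
  reason <- rep(NA_character_, nrow(tab))
  if ("valid_fraction" %in% names(tab)) {
    low <- is.na(tab$valid_fraction) | tab$valid_fraction < min_valid_fraction
    reason[low] <- "valid_fraction"
  }
  reason[is.na(tab$value) & is.na(reason)] <- "undefined"

  key <- do.call(paste, c(tab[c("variable", group_cols)], sep = "\r"))
  ok <- is.na(reason)
  for (g in unique(key)) {
    sel <- which(key == g & ok & !is.na(tab$value))
    if (length(sel) < 4) next
    q <- stats::quantile(tab$value[sel], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr <= 0) next
    out <- tab$value[sel] < q[1] - iqr_mult * iqr |
      tab$value[sel] > q[2] + iqr_mult * iqr
    reason[sel[out]] <- "outlier"
  }
  list(kept = tab[is.na(reason), , drop = FALSE],
       removed = cbind(tab[!is.na(reason), , drop = FALSE],
                       reason = reason[!is.na(reason)]))
}
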