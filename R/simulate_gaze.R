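#' Parameters for gaze-trace simulation
#'
#' Controls the generative model of a synthetic pursuit recording:
#' `eye(t) = gain * target(t - lag) + saccadic steps + noise`, with blinks
#' rendered as invalid gaps flanked by short artifact margins. Injected
#' saccades follow a minimum-jerk position profile so they exceed the
#' standard velocity/acceleration detection criteria without modeling full
#' oculomotor dynamics.
#'
#' @param saccade_rate_hz Mean rate of injected catch-up saccades (events/s).
#' @param saccade_amp_deg Mean absolute saccade amplitude in degrees.
#' @param saccade_amp_sd Between-event SD of the amplitude.
#' @param blink_rate_hz Mean blink rate (events/s).
#' @param blink_dur_ms Range (min, max) of blink durations in ms.
#' @param blink_margin_ms Duration of the artifact margin flanking each
#'   blink.
#' @param noise_sd Position noise SD in degrees.
#' @param lag_ms Constant tracking lag in ms (predictive pursuit of periodic
#'   targets shows only a small phase lag, so the default is 10 ms).
#' @return List of class `trace_sim_params`.
#' @export
trace_sim_params <- function(saccade_rate_hz = 1.0,
                             saccade_amp_deg = 2.0,
                             saccade_amp_sd = 0.5,
                             blink_rate_hz = 0.1,
                             blink_dur_ms = c(100, 250),
                             blink_margin_ms = 50,
                             noise_sd = 0.05,
                             lag_ms = 10) {
  stopifnot(saccade_rate_hz >= 0, blink_rate_hz >= 0, noise_sd >= 0,
            saccade_amp_deg >= 0, lag_ms >= 0)
  structure(list(saccade_rate_hz = saccade_rate_hz,
                 saccade_amp_deg = saccade_amp_deg,
                 saccade_amp_sd = saccade_amp_sd,
                 blink_rate_hz = blink_rate_hz,
                 blink_dur_ms = blink_dur_ms,
                 blink_margin_ms = blink_margin_ms,
                 noise_sd = noise_sd,
                 lag_ms = lag_ms),
            class = "trace_sim_params")
}

# minimum-jerk unit step profile on s in [0, 1]
min_jerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

#' Simulate one gaze trace
#'
#' @param target A [target_trajectory][generate_target].
#' @param gain Pursuit velocity gain of this recording (1 = perfect).
#' @param params A [trace_sim_params] object.
#' @param subject,occasion Identifiers carried into the trace.
#' @param seed Integer seed for this trace.
#' @return List with `trace` (a [gaze_trace]) and `events` (ground-truth log
#'   of injected saccades and blinks: `type`, `onset_ms`, `offset_ms`,
#'   `amplitude_deg`).
#' @export
simulate_gaze_trace <- function(target, gain = 1,
                                params = trace_sim_params(),
                                subject = NA, occasion = NA_integer_,
                                seed = 1L) {
  if (params$lag_ms >= target$duration_s * 1000) {
    stop("tracking lag must be shorter than the task duration", call. = FALSE)
  }
  set.seed(seed)
  t_ms <- target$times_ms
  n <- length(t_ms)
  fs <- target$sample_rate_hz
  dur_s <- target$duration_s

  eye <- gain * target_position(target, pmax(t_ms - params$lag_ms, 0))
  if (params$noise_sd > 0) eye <- eye + stats::rnorm(n, 0, params$noise_sd)

  events <- data.frame(type = character(0), onset_ms = numeric(0),
                       offset_ms = numeric(0), amplitude_deg = numeric(0))

  # blinks first so saccades can be kept clear of them
  blink_iv <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  n_blink <- stats::rpois(1, params$blink_rate_hz * dur_s)
  if (n_blink > 0) {
    on <- sort(stats::runif(n_blink, 1000, dur_s * 1000 - 1000))
    du <- stats::runif(n_blink, params$blink_dur_ms[1], params$blink_dur_ms[2])
    blink_iv <- data.frame(start_ms = on, end_ms = on + du)
    events <- rbind(events, data.frame(type = "blink", onset_ms = on,
                                       offset_ms = on + du,
                                       amplitude_deg = NA_real_))
  }
  valid <- !mask_from_intervals(t_ms, blink_iv)
  # artifact margins: fast deflections immediately around the gap
  mg <- params$blink_margin_ms
  if (nrow(blink_iv) && mg > 0) {
    for (j in seq_len(nrow(blink_iv))) {
      pre <- which(t_ms >= blink_iv$start_ms[j] - mg & t_ms < blink_iv$start_ms[j])
      post <- which(t_ms >= blink_iv$end_ms[j] & t_ms < blink_iv$end_ms[j] + mg)
      if (length(pre)) {
        eye[pre] <- eye[pre] - 3 * min_jerk(seq_along(pre) / length(pre))
      }
      if (length(post)) {
        eye[post] <- eye[post] - 3 * (1 - min_jerk(seq_along(post) / length(post)))
      }
    }
  }

  n_sacc <- stats::rpois(1, params$saccade_rate_hz * dur_s)
  if (n_sacc > 0) {
    on <- sort(stats::runif(n_sacc, 500, dur_s * 1000 - 500))
    cum <- 0
    kept_on <- kept_off <- kept_amp <- numeric(0)
    for (j in seq_len(n_sacc)) {
      amp <- abs(stats::rnorm(1, params$saccade_amp_deg, params$saccade_amp_sd))
      amp <- max(amp, 1.1)          # stay above the acceptance threshold
      sgn <- if (abs(cum) > 1) -sign(cum) else sample(c(-1, 1), 1)
      amp <- sgn * amp
      dur <- 20 + 5 * abs(amp)      # ms; peak velocity 1.875*|amp|/dur well above 60 deg/s
      off <- on[j] + dur
      # skip saccades too close to a blink or to another saccade
      clash <- nrow(blink_iv) && any(on[j] <= blink_iv$end_ms + 2 * mg &
                                       off >= blink_iv$start_ms - 2 * mg)
      if (clash || (length(kept_off) && on[j] < kept_off[length(kept_off)] + 100)) next
      idx <- which(t_ms >= on[j] & t_ms <= off)
      if (!length(idx)) next
      prof <- amp * min_jerk((t_ms[idx] - on[j]) / dur)
      eye[idx] <- eye[idx] + prof
      if (max(idx) < n) eye[(max(idx) + 1):n] <- eye[(max(idx) + 1):n] + amp
      cum <- cum + amp
      kept_on <- c(kept_on, on[j]); kept_off <- c(kept_off, off)
      kept_amp <- c(kept_amp, amp)
    }
    if (length(kept_on)) {
      events <- rbind(events, data.frame(type = "saccade", onset_ms = kept_on,
                                         offset_ms = kept_off,
                                         amplitude_deg = kept_amp))
    }
  }
  events <- events[order(events$onset_ms), , drop = FALSE]
  list(trace = gaze_trace(t_ms, eye, valid, subject = subject,
                          occasion = occasion, task = target$pattern),
       events = events)
}

# per-subject substream: deterministic, independent of how many other
# subjects were simulated before
subject_seed <- function(seed, subject, occasion = 1L, task = 1L) {
  s <- (as.numeric(seed) * 7919 + subject * 104729 +
          occasion * 1299709 + task * 15485863) %% 2147483647
  as.integer(s)
}

#' Simulate a full multi-subject gaze dataset
#'
#' Generates one trace per subject x occasion x task with subject gains
#' driven by a latent trait/state structure: subject `s` at occasion `i`
#' pursues with gain `trait_gain_s + state_dev_si`, where trait gains are
#' `N(gain_mean, gain_trait_sd^2)` and occasion deviations are
#' `N(0, gain_state_sd^2)`. Each trace gets its own deterministic substream
#' of the global seed, so any single trace can be regenerated in isolation.
#'
#' @param targets Named list of [target_trajectory][generate_target] objects
#'   (one per task).
#' @param n_subjects Number of subjects.
#' @param n_occasions Number of occasions.
#' @param gain_mean,gain_trait_sd,gain_state_sd Gain structure (gain scale:
#'   1 = 100%).
#' @param trace_params A [trace_sim_params] object.
#' @param seed Global integer seed.
#' @return List with `traces` (nested list `[[task]][[subject]][[occasion]]`),
#'   `events` (combined ground-truth event log), and `gains` (data frame of
#'   true trait gains and per-occasion gains).
#' @export
simulate_gaze_dataset <- function(targets, n_subjects, n_occasions = 3,
                                  gain_mean = 0.92, gain_trait_sd = 0.05,
                                  gain_state_sd = 0.02,
                                  trace_params = trace_sim_params(),
                                  seed = 1L) {
  set.seed(seed)
  trait_gain <- stats::rnorm(n_subjects, gain_mean, gain_trait_sd)
  state_dev <- matrix(stats::rnorm(n_subjects * n_occasions, 0, gain_state_sd),
                      n_subjects, n_occasions)
  gains <- data.frame(subject = seq_len(n_subjects), trait_gain = trait_gain)
  for (i in seq_len(n_occasions)) {
    gains[[sprintf("gain_t%d", i)]] <- trait_gain + state_dev[, i]
  }
  traces <- list()
  ev_all <- list()
  for (ti in seq_along(targets)) {
    task <- names(targets)[ti]
    traces[[task]] <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      traces[[task]][[s]] <- vector("list", n_occasions)
      for (i in seq_len(n_occasions)) {
        sim <- simulate_gaze_trace(
          targets[[ti]], gain = trait_gain[s] + state_dev[s, i],
          params = trace_params, subject = s, occasion = i,
          seed = subject_seed(seed, s, i, ti))
        traces[[task]][[s]][[i]] <- sim$trace
        if (nrow(sim$events)) {
          ev_all[[length(ev_all) + 1L]] <-
            cbind(subject = s, occasion = i, task = task, sim$events)
        }
      }
    }
  }
  list(traces = traces,
       events = if (length(ev_all)) do.call(rbind, ev_all) else NULL,
       gains = gains)
}
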