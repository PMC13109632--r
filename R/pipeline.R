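#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages simulate -> metrics -> fit -> decompose ->
#' classical on synthetic data with known ground truth. Every stage writes
#' its outputs as CSV/JSON under `out_dir`, and a manifest records the
#' configuration, seeds and file hashes. Reruns with `overwrite = FALSE`
#' skip stages whose outputs already exist.
#'
#' @param config Path to a YAML configuration file or an equivalent named
#'   list. See [default_config()] for the schema and defaults; unknown keys
#'   are rejected before any computation.
#' @param overwrite Recompute stages whose outputs already exist.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, overwrite = TRUE) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  res <- list(config = cfg)
  log_msg <- function(...) message(sprintf(...))

  path_of <- function(name) file.path(out_dir, name)
  done <- function(name) !overwrite && file.exists(path_of(name))

  targets <- lapply(cfg$design$tasks, function(task) {
    generate_target(task, sample_rate_hz = cfg$design$sample_rate_hz)
  })
  names(targets) <- cfg$design$tasks

  ## ---- simulate -----------------------------------------------------------
  if ("simulate" %in% stages) {
    log_msg("[simulate] %d subjects x %d occasions x %d task(s)",
            cfg$design$n_subjects, cfg$design$n_occasions, length(targets))
    sim <- simulate_gaze_dataset(
      targets, cfg$design$n_subjects, cfg$design$n_occasions,
      gain_mean = cfg$gain$mean, gain_trait_sd = cfg$gain$trait_sd,
      gain_state_sd = cfg$gain$state_sd,
      trace_params = do.call(trace_sim_params, cfg$trace),
      seed = cfg$seed)
    res$simulate <- sim
    utils::write.csv(sim$gains, path_of("true_gains.csv"), row.names = FALSE)
    if (!is.null(sim$events)) {
      utils::write.csv(sim$events, path_of("event_log.csv"), row.names = FALSE)
    }
  }

  ## ---- metrics ------------------------------------------------------------
  if ("metrics" %in% stages) {
    if (is.null(res$simulate)) stop("metrics stage needs the simulate stage",
                                    call. = FALSE)
    if (done("metrics.csv")) {
      log_msg("[metrics] outputs exist; skipped")
      res$metrics <- utils::read.csv(path_of("metrics.csv"))
    } else {
      log_msg("[metrics] extracting pursuit metrics")
      th <- cfg$thresholds
      all_rows <- list()
      hc_rows <- list()
      for (task in names(targets)) {
        for (s in seq_len(cfg$design$n_subjects)) {
          for (i in seq_len(cfg$design$n_occasions)) {
            tm <- trace_metrics(res$simulate$traces[[task]][[s]][[i]],
                                targets[[task]], k = cfg$model$n_indicators,
                                vel_high = th$vel_high, vel_low = th$vel_low,
                                accel = th$accel,
                                min_amplitude = th$min_amplitude,
                                blink_margin_ms = th$blink_margin_ms,
                                min_segment_ms = th$min_segment_ms,
                                central_frac = th$central_frac)
            m <- tm$metrics
            m$subject <- s; m$occasion <- i; m$task <- task
            all_rows[[length(all_rows) + 1L]] <- m
            h <- tm$half_cycle_values
            h$subject <- s; h$occasion <- i; h$task <- task
            hc_rows[[length(hc_rows) + 1L]] <- h
          }
        }
      }
      metrics <- do.call(rbind, all_rows)
      excl <- apply_exclusions(metrics,
                               min_valid_fraction = th$min_valid_fraction,
                               iqr_mult = th$iqr_mult)
      res$metrics <- excl$kept
      res$metrics_removed <- excl$removed
      res$half_cycles <- do.call(rbind, hc_rows)
      utils::write.csv(excl$kept, path_of("metrics.csv"), row.names = FALSE)
      utils::write.csv(excl$removed, path_of("metrics_removed.csv"),
                       row.names = FALSE)
      utils::write.csv(res$half_cycles, path_of("half_cycle_values.csv"),
                       row.names = FALSE)
    }
  }

  ## ---- fit + decompose ----------------------------------------------------
  if (any(c("fit", "decompose") %in% stages)) {
    if (is.null(res$metrics)) stop("fit stage needs the metrics stage",
                                   call. = FALSE)
    log_msg("[fit] model selection per task x variable")
    res$fits <- list()
    dec_rows <- list()
    for (task in unique(res$metrics$task)) {
      for (v in cfg$model$variables) {
        wide <- metric_wide(res$metrics, task, v, cfg$model$n_indicators,
                            cfg$design$n_occasions,
                            n_subjects = cfg$design$n_subjects)
        md <- tryCatch(mardia_test(wide), error = function(e) NULL)
        use_robust <- switch(cfg$model$robust,
                             always = TRUE, never = FALSE,
                             auto = !is.null(md) && !md$normal)
        sel <- tryCatch(
          select_model(wide, n_indicators = cfg$model$n_indicators,
                       n_occasions = cfg$design$n_occasions,
                       robust = use_robust, restarts = cfg$model$restarts),
          error = function(e) NULL)
        key <- paste(task, v, sep = ".")
        res$fits[[key]] <- list(mardia = md, robust = use_robust,
                                selection = sel)
        if ("decompose" %in% stages && !is.null(sel) && !is.null(sel$fit) &&
            sel$family %in% c("LST", "LST_T", "LGC")) {
          dc <- decompose_fit(sel$fit)
          avg <- average_decomposition(dc)
          dec_rows[[key]] <- data.frame(task = task, variable = v,
                                        family = sel$family,
                                        rel = avg$rel, con = avg$con,
                                        spe = avg$spe)
        }
      }
    }
    if (length(dec_rows)) {
      dec <- do.call(rbind, dec_rows)
      dec$variable_label <- paste(dec$task, dec$variable, sep = ".")
      summ <- summarize_decomposition(
        data.frame(variable = dec$variable_label, rel = dec$rel,
                   con = dec$con, spe = dec$spe))
      res$decomposition <- dec
      res$decomposition_summary <- summ
      utils::write.csv(dec, path_of("decomposition.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(grand = summ$grand, extrema = summ$extrema),
        path_of("decomposition_summary.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  ## ---- classical ----------------------------------------------------------
  if ("classical" %in% stages) {
    if (is.null(res$metrics)) stop("classical stage needs the metrics stage",
                                   call. = FALSE)
    log_msg("[classical] CTT reliability and repeated-measures tests")
    rows <- list()
    for (task in unique(res$metrics$task)) {
      for (v in cfg$model$variables) {
        occ <- metric_occasions(res$metrics, task, v,
                                cfg$design$n_occasions,
                                n_subjects = cfg$design$n_subjects)
        icc <- tryCatch(icc_a1(occ), error = function(e) NULL)
        an <- tryCatch(rm_anova(occ), error = function(e) NULL)
        al <- NA_real_
        if (!is.null(res$half_cycles) && v %in% c("gain", "rmse")) {
          hw <- halfcycle_wide(res$half_cycles, task, v, occasion = 1L,
                               n_subjects = cfg$design$n_subjects)
          a <- cronbach_alpha_equalized(hw, seed = cfg$seed + 17L,
                                        min_items = cfg$classical$alpha_min_items)
          al <- a$alpha
        }
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, variable = v,
          icc = if (is.null(icc)) NA_real_ else icc$icc,
          icc_lower = if (is.null(icc)) NA_real_ else icc$lower,
          icc_upper = if (is.null(icc)) NA_real_ else icc$upper,
          f = if (is.null(an)) NA_real_ else an$f,
          p_governing = if (is.null(an)) NA_real_ else an$p_governing,
          eta_p2 = if (is.null(an)) NA_real_ else an$eta_p2,
          alpha_t1 = al)
      }
    }
    res$classical <- do.call(rbind, rows)
    utils::write.csv(res$classical, path_of("classical.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pursuitlst")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    files = file_hashes(out_dir))
  jsonlite::write_json(manifest, path_of("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

file_hashes <- function(dir) {
  fs <- list.files(dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  fs <- fs[basename(fs) != "manifest.json"]
  as.list(tools::md5sum(fs))
}

#' Default pipeline configuration
#'
#' The complete configuration schema with its defaults. All signal-stage
#' thresholds default to the standard analysis values (velocity 60 deg/s or
#' 22 deg/s with acceleration 3800 deg/s^2; amplitude 1 deg; 50 ms minimum
#' gain segments in the central 50% of each half-cycle; 50% minimum valid
#' time; 4 x IQR outlier fences).
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "pursuitlst-run",
    stages = c("simulate", "metrics", "fit", "decompose", "classical"),
    design = list(n_subjects = 50L, n_occasions = 3L,
                  tasks = "sinusoidal", sample_rate_hz = 1000),
    gain = list(mean = 0.92, trait_sd = 0.05, state_sd = 0.02),
    trace = list(saccade_rate_hz = 1.0, saccade_amp_deg = 2.0,
                 saccade_amp_sd = 0.5, blink_rate_hz = 0.1,
                 blink_dur_ms = c(100, 250), blink_margin_ms = 50,
                 noise_sd = 0.05, lag_ms = 10),
    thresholds = list(vel_high = 60, vel_low = 22, accel = 3800,
                      min_amplitude = 1.0, blink_margin_ms = 100,
                      min_segment_ms = 50, central_frac = 0.5,
                      min_valid_fraction = 0.5, iqr_mult = 4),
    model = list(n_indicators = 2L, robust = "auto", restarts = 3L,
                 variables = c("gain", "sd_gain", "rmse", "sd_rmse",
                               "sacc_freq")),
    classical = list(alpha_min_items = 30L)
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(def, config)
  for (grp in c("design", "gain", "trace", "thresholds", "model", "classical")) {
    bad <- setdiff(names(cfg[[grp]]), names(def[[grp]]))
    if (length(bad)) {
      stop(sprintf("unknown configuration key(s) in `%s`: %s", grp,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  bad_stage <- setdiff(cfg$stages, def$stages)
  if (length(bad_stage)) {
    stop(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")),
         call. = FALSE)
  }
  bad_task <- setdiff(cfg$design$tasks, c("sinusoidal", "triangular"))
  if (length(bad_task)) {
    stop(sprintf("unknown task(s): %s", paste(bad_task, collapse = ", ")),
         call. = FALSE)
  }
  cfg
}

# subject x (occasion-major indicator) wide matrix for one task/variable
metric_wide <- function(metrics, task, variable, n_indicators, n_occasions,
                        n_subjects) {
  sub <- metrics[metrics$task == task & metrics$variable == variable &
                   metrics$set > 0, , drop = FALSE]
  cols <- manifest_names(n_occasions, n_indicators)
  out <- matrix(NA_real_, n_subjects, length(cols), dimnames = list(NULL, cols))
  for (r in seq_len(nrow(sub))) {
    cn <- sprintf("x%d_%d", sub$occasion[r], sub$set[r])
    out[sub$subject[r], cn] <- sub$value[r]
  }
  out
}

# subject x occasion matrix of the whole-occasion aggregate (set == 0)
metric_occasions <- function(metrics, task, variable, n_occasions,
                             n_subjects) {
  sub <- metrics[metrics$task == task & metrics$variable == variable &
                   metrics$set == 0, , drop = FALSE]
  out <- matrix(NA_real_, n_subjects, n_occasions)
  for (r in seq_len(nrow(sub))) {
    out[sub$subject[r], sub$occasion[r]] <- sub$value[r]
  }
  out
}

# subject x half-cycle matrix of per-half-cycle values at one occasion
halfcycle_wide <- function(half_cycles, task, variable, occasion,
                           n_subjects) {
  sub <- half_cycles[half_cycles$task == task &
                       half_cycles$occasion == occasion, , drop = FALSE]
  n_hc <- max(sub$half_cycle)
  out <- matrix(NA_real_, n_subjects, n_hc)
  vals <- sub[[variable]]
  ok <- sub$valid_fraction >= 0.5 & !is.na(vals)
  out[cbind(sub$subject[ok], sub$half_cycle[ok])] <- vals[ok]
  out
}
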