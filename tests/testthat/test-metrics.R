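test_that("perfect tracking gives gain 100, sd_gain 0, rmse 0, sd_rmse 0", {
  tgt <- paper_sinusoid()
  hc <- segment_half_cycles(tgt)
  tr <- gaze_trace(tgt$times_ms, tgt$positions)
  g <- compute_gain(tr, tgt, hc)
  r <- compute_rmse(tr, tgt, hc)
  expect_equal(g$gain_pct, 100, tolerance = 0.05)
  expect_lt(g$sd_gain_pct, 1e-6)
  expect_equal(r$rmse_deg, 0)
  expect_equal(r$sd_rmse_deg, 0)
  expect_equal(g$valid_fraction, 1)
})

test_that("a uniformly scaled trace yields the scaling as gain (both tasks)", {
  for (tgt in list(paper_sinusoid(), paper_triangle())) {
    hc <- segment_half_cycles(tgt)
    tr <- gaze_trace(tgt$times_ms, 0.9 * tgt$positions)
    g <- compute_gain(tr, tgt, hc)
    expect_equal(g$gain_pct, 90, tolerance = 0.5)
    expect_lt(g$sd_gain_pct, 0.5)
  }
})

test_that("a constant 1-degree offset gives RMSE exactly 1", {
  tgt <- paper_sinusoid()
  hc <- segment_half_cycles(tgt)
  tr <- gaze_trace(tgt$times_ms, tgt$positions + 1)
  r <- compute_rmse(tr, tgt, hc)
  expect_equal(r$rmse_deg, 1, tolerance = 1e-12)
  expect_lt(r$sd_rmse_deg, 1e-12)
})

test_that("valid runs shorter than 50 ms contribute nothing to gain", {
  tgt <- generate_target("sinusoidal", duration_s = 5)
  hc <- segment_half_cycles(tgt)
  tr <- gaze_trace(tgt$times_ms, tgt$positions)
  # exclude everything except one 48 ms run inside the central window
  excl <- rep(TRUE, length(tgt$positions))
  mid <- (hc$start_ms[1] + hc$end_ms[1]) / 2
  run <- tgt$times_ms >= mid & tgt$times_ms < mid + 48
  excl[run] <- FALSE
  g <- compute_gain(tr, tgt, hc[1, ], exclude = excl)
  expect_true(is.na(g$gain_pct))
  expect_equal(g$valid_fraction, 0)
  # at 52 ms the run qualifies
  excl2 <- rep(TRUE, length(tgt$positions))
  excl2[tgt$times_ms >= mid & tgt$times_ms < mid + 52] <- FALSE
  g2 <- compute_gain(tr, tgt, hc[1, ], exclude = excl2)
  expect_equal(g2$gain_pct, 100, tolerance = 0.1)
})

test_that("masked RMSE equals a brute-force weighted RMS over the same samples", {
  set.seed(9)
  tgt <- generate_target("triangular", duration_s = 12)
  hc <- segment_half_cycles(tgt)
  eye <- tgt$positions + rnorm(length(tgt$positions), 0, 0.3)
  tr <- gaze_trace(tgt$times_ms, eye)
  excl <- runif(length(eye)) < 0.3
  r <- compute_rmse(tr, tgt, hc, exclude = excl)
  # oracle: direct re-summation over included samples inside half-cycles
  inside <- rep(FALSE, length(eye))
  for (j in seq_len(nrow(hc))) {
    inside <- inside | (tgt$times_ms >= hc$start_ms[j] &
                          tgt$times_ms < hc$end_ms[j])
  }
  sel <- inside & !excl
  oracle <- sqrt(mean((eye[sel] - tgt$positions[sel])^2))
  expect_equal(r$rmse_deg, oracle, tolerance = 1e-12)
})

test_that("gain is invariant to injecting detected-and-excluded saccades", {
  tgt <- paper_sinusoid()
  hc <- segment_half_cycles(tgt)
  clean <- simulate_gaze_trace(tgt, gain = 0.9, params = clean_trace_params(),
                               seed = 1)
  tm_clean <- trace_metrics(clean$trace, tgt)
  with_sacc <- simulate_gaze_trace(
    tgt, gain = 0.9,
    params = trace_sim_params(saccade_rate_hz = 0.5, blink_rate_hz = 0,
                              noise_sd = 0, lag_ms = 0),
    seed = 1)
  tm_sacc <- trace_metrics(with_sacc$trace, tgt)
  g0 <- tm_clean$metrics$value[tm_clean$metrics$variable == "gain" &
                                 tm_clean$metrics$set == 0]
  g1 <- tm_sacc$metrics$value[tm_sacc$metrics$variable == "gain" &
                                tm_sacc$metrics$set == 0]
  expect_equal(g1, g0, tolerance = 0.5)
})

test_that("saccade frequency arithmetic and sentinels", {
  ev <- data.frame(near_blink = c(rep(FALSE, 18), TRUE, TRUE))
  expect_equal(compute_saccade_frequency(ev, 90), 0.20)
  expect_equal(compute_saccade_frequency(ev[0, , drop = FALSE], 60), 0)
  expect_true(is.na(compute_saccade_frequency(ev, 0)))
  ev60 <- data.frame(near_blink = rep(FALSE, 60))
  expect_equal(compute_saccade_frequency(ev60, 60), 1.0)
})

test_that("exclusion rules drop low-validity cells and planted outliers only", {
  set.seed(3)
  tab <- data.frame(variable = "gain", occasion = 1, set = 1,
                    value = rnorm(40, 90, 2), valid_fraction = 1)
  tab$valid_fraction[5] <- 0.49
  q <- quantile(tab$value[-5], c(0.25, 0.75))
  iqr <- q[2] - q[1]
  tab$value[10] <- q[2] + 5 * iqr                     # planted outlier
  res <- apply_exclusions(tab)
  expect_equal(sort(res$removed$reason), c("outlier", "valid_fraction"))
  expect_equal(which(tab$valid_fraction < 0.5), 5)
  expect_false(10 %in% as.integer(rownames(res$kept)))
  expect_equal(nrow(res$kept), 38)

  # zero IQR: identical values are never flagged
  tab2 <- data.frame(variable = "rmse", occasion = 1, set = 1,
                     value = rep(1.5, 20), valid_fraction = 1)
  res2 <- apply_exclusions(tab2)
  expect_equal(nrow(res2$removed), 0)
})

test_that("trace_metrics produces per-set and whole-occasion rows plus half-cycle values", {
  tgt <- paper_sinusoid()
  sim <- simulate_gaze_trace(tgt, gain = 0.95, seed = 12)
  tm <- trace_metrics(sim$trace, tgt, k = 2)
  expect_setequal(unique(tm$metrics$set), 0:2)
  expect_setequal(unique(tm$metrics$variable),
                  c("gain", "sd_gain", "rmse", "sd_rmse", "sacc_freq"))
  expect_equal(nrow(tm$half_cycle_values), 60)
  expect_true(all(tm$half_cycle_values$valid_fraction <= 1))
})
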