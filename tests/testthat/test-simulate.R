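test_that("latent simulation is deterministic and validates parameters", {
  p <- study_latent_params(50, seed = 99)
  d1 <- simulate_latent_dataset(p)
  d2 <- simulate_latent_dataset(p)
  expect_identical(d1, d2)
  expect_error(latent_sim_params(10, trait_var = -1), "variances")
  expect_error(latent_sim_params(10, missing_rate = 1), "missing_rate")
  expect_error(latent_sim_params(10, n_indicators = 5), "2-4")
  expect_error(latent_sim_params(10, trait_var = 1, slope_var = 1,
                                 trait_slope_cov = 2), "trait_slope_cov")
})

test_that("noise-free, state-free subjects are constant across occasions", {
  p <- latent_sim_params(20, trait_var = 2, state_residual_vars = 0,
                         error_vars = 0, slope_loadings = 0, seed = 5)
  d <- simulate_latent_dataset(p)
  x <- as.matrix(d$data[, -1])
  expect_lt(max(apply(x, 1, function(r) diff(range(r)))), 1e-12)
  # and equal to the trait draw itself
  expect_equal(x[, 1], d$truth$trait)
})

test_that("sample moments converge to the model-implied covariance", {
  p <- study_latent_params(1e5, seed = 31)
  d <- simulate_latent_dataset(p)
  pop <- latent_population_moments(p)
  x <- as.matrix(d$data[, -1])
  s <- cov(x)
  # approximate SE of a covariance entry is ~ sqrt((s_ii s_jj + s_ij^2)/n)
  n <- nrow(x)
  se <- sqrt((outer(diag(pop$sigma), diag(pop$sigma)) + pop$sigma^2) / n)
  expect_lt(max(abs(s - pop$sigma) / se), 5)
  expect_lt(max(abs(colMeans(x) - pop$mu)), 4 * sqrt(max(diag(pop$sigma)) / n))
  # population shares for the study condition
  expect_equal(pop$shares$con[1], 4 / 5.68, tolerance = 1e-12)
  expect_equal(pop$shares$spe[1], 1.6 / 5.68, tolerance = 1e-12)
})

test_that("occasions are exchangeable with unit loadings and no slope", {
  p <- study_latent_params(4e4, seed = 8)
  d <- simulate_latent_dataset(p)
  x <- as.matrix(d$data[, -1])
  occ_var <- sapply(1:3, function(i) mean(apply(x[, (i - 1) * 2 + 1:2], 2, var)))
  expect_lt(diff(range(occ_var)) / mean(occ_var), 0.05)
  occ_mean <- sapply(1:3, function(i) mean(x[, (i - 1) * 2 + 1:2]))
  expect_lt(diff(range(occ_mean)), 4 * sqrt(5.68 / 4e4) * 3)
})

test_that("MCAR missingness is independent of the values", {
  p <- study_latent_params(2e4, seed = 77, missing_rate = 0.25)
  d <- simulate_latent_dataset(p)
  p_full <- study_latent_params(2e4, seed = 77)
  d_full <- simulate_latent_dataset(p_full)
  x <- as.matrix(d$data[, -1])
  miss_frac <- mean(is.na(x))
  expect_equal(miss_frac, 0.25, tolerance = 0.01)
  # observed-mean vs full-data mean differ only by Monte-Carlo error
  mo <- colMeans(x, na.rm = TRUE)
  mf <- colMeans(as.matrix(d_full$data[, -1])[!is.na(x[, 1]) | TRUE, ])
  expect_lt(max(abs(mo - mf)), 4 * sqrt(5.68 / (2e4 * 0.75)))
})

test_that("clean gaze simulation reproduces the target exactly at gain 1", {
  tgt <- generate_target("sinusoidal", duration_s = 10)
  sim <- simulate_gaze_trace(tgt, gain = 1, params = clean_trace_params(),
                             seed = 2)
  expect_equal(sim$trace$x, tgt$positions, tolerance = 1e-12)
  expect_true(all(sim$trace$valid))
  expect_equal(nrow(sim$events), 0)
})

test_that("the saccade detector recovers the injected event log", {
  tgt <- paper_sinusoid()
  sim <- simulate_gaze_trace(
    tgt, gain = 0.9,
    params = trace_sim_params(saccade_rate_hz = 0.25, blink_rate_hz = 0,
                              noise_sd = 0, lag_ms = 0),
    seed = 21)
  inj <- sim$events[sim$events$type == "saccade", ]
  tm <- trace_metrics(sim$trace, tgt)
  expect_equal(nrow(tm$events), nrow(inj))
  matched <- vapply(inj$onset_ms, function(o) {
    any(abs(tm$events$onset_ms - o) < 40)
  }, logical(1))
  expect_true(all(matched))
})

test_that("per-subject substreams reproduce a trace in isolation", {
  tgt <- generate_target("sinusoidal", duration_s = 6)
  ds <- simulate_gaze_dataset(list(sinusoidal = tgt), n_subjects = 3,
                              n_occasions = 2, seed = 7)
  lone <- simulate_gaze_trace(
    tgt, gain = ds$gains$gain_t2[2], params = trace_sim_params(),
    subject = 2, occasion = 2,
    seed = pursuitlst:::subject_seed(7, 2, 2, 1))
  expect_identical(ds$traces$sinusoidal[[2]][[2]]$x, lone$trace$x)
})

test_that("end-to-end measured gains rank-correlate with true subject gains", {
  tgt <- generate_target("sinusoidal", duration_s = 20)
  hc <- segment_half_cycles(tgt)
  true_g <- seq(0.80, 1.00, length.out = 9)
  meas <- vapply(seq_along(true_g), function(j) {
    sim <- simulate_gaze_trace(
      tgt, gain = true_g[j],
      params = trace_sim_params(saccade_rate_hz = 0.6, blink_rate_hz = 0.1,
                                noise_sd = 0.05, lag_ms = 0),
      seed = 100 + j)
    tm <- trace_metrics(sim$trace, tgt)
    tm$metrics$value[tm$metrics$variable == "gain" & tm$metrics$set == 0]
  }, numeric(1))
  expect_gt(cor(true_g, meas, method = "spearman"), 0.99)
})

test_that("gaze CSV and mask round-trips preserve the trace", {
  tgt <- generate_target("triangular", duration_s = 4)
  sim <- simulate_gaze_trace(tgt, gain = 0.95, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_gaze_csv(sim$trace, f)
  back <- read_gaze_csv(f, subject = 1, occasion = 2, task = "triangular")
  expect_equal(back$x, sim$trace$x)
  expect_equal(back$valid, sim$trace$valid)
  m <- data.frame(start_ms = c(100, 900), end_ms = c(200, 1000))
  fm <- tempfile(fileext = ".csv")
  write_mask_csv(m, fm)
  expect_equal(read_mask_csv(fm), m)
  expect_equal(nrow(read_mask_csv(tempfile())), 0)
  unlink(c(f, fm))
})
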