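# shared fixtures, built in code

# the two standard task geometries (1000 Hz); generated once per test run
paper_sinusoid <- function() generate_target("sinusoidal")
paper_triangle <- function() generate_target("triangular")

# quiet simulation params: no saccades, no blinks, no noise, no lag
clean_trace_params <- function(...) {
  trace_sim_params(saccade_rate_hz = 0, blink_rate_hz = 0, noise_sd = 0,
                   lag_ms = 0, ...)
}

# the study-condition latent population: Con = 4/5.68 ~ 0.704,
# Spe = 1.6/5.68 ~ 0.282 (lambda = gamma = 1)
study_latent_params <- function(n, seed, ...) {
  latent_sim_params(n, trait_var = 4, state_residual_vars = 1.6,
                    error_vars = 0.08, slope_loadings = 0, seed = seed, ...)
}

# brute-force reversal scan: sign changes of the finite-difference velocity
oracle_reversals <- function(positions) {
  v <- diff(positions)
  s <- sign(v)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  which(diff(s) != 0) + 1L
}

zoo_locf <- function(x) {
  last <- NA
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  x
}
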