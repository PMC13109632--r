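test_that("decomposition reproduces the hand-computed variance shares", {
  d <- simulate_latent_dataset(study_latent_params(3000, seed = 91))
  f <- fit_ml(lst_model_spec("LST_T", 2, restriction = "C"), d$data,
              restarts = 2)
  dc <- decompose_fit(f)
  # population: Con = 4/5.68 ~ 0.704, Spe = 1.6/5.68 ~ 0.282, Rel ~ 0.986
  expect_equal(mean(dc$con), 4 / 5.68, tolerance = 0.03)
  expect_equal(mean(dc$spe), 1.6 / 5.68, tolerance = 0.03)
  expect_equal(mean(dc$rel), 5.6 / 5.68, tolerance = 0.02)
})

test_that("the Rel = Con + Spe identity holds to numerical precision", {
  for (seed in c(93, 95)) {
    d <- simulate_latent_dataset(study_latent_params(300, seed = seed))
    for (r in c("none", "C")) {
      f <- fit_ml(lst_model_spec("LST_T", 2, restriction = r), d$data,
                  restarts = 2)
      dc <- decompose_fit(f)
      expect_lt(max(abs(dc$rel - dc$con - dc$spe)), 1e-12)
      # 1 - Rel equals the error share under the fitted model
      eps_share <- as.vector(t(f$params$eps)) / diag(f$implied$sigma)
      expect_lt(max(abs((1 - dc$rel) - eps_share)), 1e-10)
    }
  }
})

test_that("zero state-residual variance collapses specificity to zero", {
  p <- latent_sim_params(500, trait_var = 4, state_residual_vars = 0,
                         error_vars = 0.4, slope_loadings = 0, seed = 97)
  d <- simulate_latent_dataset(p)
  f <- fit_ml(lst_model_spec("LST_T", 2, restriction = "C"), d$data,
              restarts = 2)
  dc <- decompose_fit(f)
  expect_lt(max(abs(dc$spe)), 0.05)
  expect_equal(dc$rel, dc$con + dc$spe, tolerance = 1e-12)
})

test_that("a degenerate LGC decomposition equals the LST formula", {
  d <- simulate_latent_dataset(study_latent_params(800, seed = 101))
  f_lgc <- fit_ml(lst_model_spec("LGC", 2, restriction = "C", sigma3 = 2),
                  d$data, restarts = 3)
  st <- f_lgc$params
  # rebuild Eq-2-style consistency ignoring the (near-zero) slope terms
  dc <- decompose_fit(f_lgc)
  con_lst <- st$gamma[1]^2 * st$var_t / diag(f_lgc$implied$sigma)[1]
  expect_equal(dc$con[1], con_lst +
                 (st$sigma[1]^2 * st$var_sl +
                    2 * st$gamma[1] * st$sigma[1] * st$cov_tsl) /
                 diag(f_lgc$implied$sigma)[1], tolerance = 1e-12)
  # occasion 1 has slope loading 0, so its consistency is exactly the trait share
  expect_equal(dc$con[1], con_lst, tolerance = 1e-12)
})

test_that("decomposition refuses families without state residuals", {
  d <- simulate_latent_dataset(study_latent_params(150, seed = 103))
  f_lt <- fit_ml(lst_model_spec("LT", 2, restriction = "A"), d$data,
                 restarts = 1)
  expect_error(decompose_fit(f_lt), "LST/LST_T/LGC")
  f_ls <- fit_ml(lst_model_spec("LS", 2, mi_level = "strict"), d$data,
                 restarts = 1)
  expect_error(decompose_fit(f_ls), "LST/LST_T/LGC")
})

test_that("summaries over the reference table reproduce the published aggregates", {
  ref <- reference_decomposition()
  expect_equal(nrow(ref), 10)
  sm <- summarize_decomposition(
    data.frame(variable = paste(ref$task, ref$variable, sep = "."),
               rel = ref$rel, con = ref$con, spe = ref$spe))
  expect_equal(round(sm$grand$con, 2), 0.62)
  expect_equal(round(sm$grand$spe, 2), 0.26)
  expect_equal(round(sm$grand$trait_share_pct), 70)
  shares <- sm$per_variable
  get <- function(v) shares$trait_share_pct_0[shares$variable == v]
  expect_equal(get("sinusoidal.sacc_freq"), 81)
  expect_equal(get("triangular.sacc_freq"), 82)
  expect_equal(get("sinusoidal.gain"), 71)
  expect_equal(get("triangular.gain"), 70)
  expect_equal(sm$extrema$con_range, c(0.48, 0.76))
  expect_equal(sm$extrema$spe_range, c(0.17, 0.38))
  expect_equal(sm$extrema$rel_range[1], 0.70)
})

test_that("a single-variable summary is the variable itself", {
  sm <- summarize_decomposition(
    data.frame(variable = "gain", rel = 0.9, con = 0.6, spe = 0.3))
  expect_equal(sm$grand$con, 0.6)
  expect_equal(sm$grand$trait_share_pct, 100 * 0.6 / 0.9)
})
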