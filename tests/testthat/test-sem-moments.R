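test_that("LST implied moments match the hand-computed values", {
  spec <- lst_model_spec("LST_T", n_indicators = 2, restriction = "C")
  th <- c(var_t = 4, var_sr = 1.6, eps = 0.08, mu_t = 0)[spec$free_labels]
  m <- implied_moments(spec, th)
  expect_equal(diag(m$sigma), rep(5.68, 6))
  # within-occasion cross-indicator covariance: VarT + VarSR
  expect_equal(m$sigma[1, 2], 5.6)
  # cross-occasion covariance: VarT only
  expect_equal(m$sigma[1, 3], 4)
  expect_equal(m$sigma[1, 6], 4)
  expect_true(isSymmetric(m$sigma))
  expect_true(all(eigen(m$sigma, only.values = TRUE)$values > 0))
})

test_that("LT with equal errors implies compound symmetry across all indicators", {
  spec <- lst_model_spec("LT", n_indicators = 2, restriction = "C")
  th <- c(var_t = 2, eps = 0.5, mu_t = 1)[spec$free_labels]
  m <- implied_moments(spec, th)
  off <- m$sigma[upper.tri(m$sigma)]
  expect_true(all(abs(off - 2) < 1e-12))
  expect_true(all(abs(diag(m$sigma) - 2.5) < 1e-12))
  expect_equal(m$mu, rep(1, 6))
})

test_that("LGC with zero slope variance reduces to LST_T implied moments", {
  sp_lgc <- lst_model_spec("LGC", n_indicators = 2, restriction = "C",
                           sigma3 = 2)
  th_lgc <- c(var_t = 4, var_sr = 1.6, eps = 0.08, mu_t = 0.5, mu_sl = 0,
              var_sl = 0, cov_tsl = 0)[sp_lgc$free_labels]
  sp_lst <- lst_model_spec("LST_T", n_indicators = 2, restriction = "C")
  th_lst <- c(var_t = 4, var_sr = 1.6, eps = 0.08, mu_t = 0.5)[sp_lst$free_labels]
  m1 <- implied_moments(sp_lgc, th_lgc)
  m2 <- implied_moments(sp_lst, th_lst)
  expect_equal(m1$sigma, m2$sigma, tolerance = 1e-12)
  expect_equal(m1$mu, m2$mu, tolerance = 1e-12)
})

test_that("free-parameter counts reproduce the published model degrees of freedom", {
  # 6 manifest variables: 27 observed moments (6 means + 21 covariances)
  df_of <- function(spec) 27 - spec$npar
  expect_equal(df_of(lst_model_spec("LST_T", 2, restriction = "A")), 18)
  expect_equal(df_of(lst_model_spec("LST_T", 2, restriction = "B")), 22)
  expect_equal(df_of(lst_model_spec("LST_T", 2, restriction = "C")), 23)
  expect_equal(df_of(lst_model_spec("LST_T", 2, restriction = "none")), 13)
  expect_equal(df_of(lst_model_spec("LST", 2, restriction = "none")), 11)
  # LGC ladder C with a free third slope loading
  expect_equal(df_of(lst_model_spec("LGC", 2, restriction = "C")), 19)
  # ... and with it fixed (the negative-slope-variance remedy)
  expect_equal(df_of(lst_model_spec("LGC", 2, restriction = "C",
                                    sigma3 = 0.92)), 20)
  # 3-indicator models: 54 moments
  sp3 <- lst_model_spec("LST_T", 3, restriction = "C")
  expect_equal(54 - sp3$npar, 50)
  # fixing an error variance to zero frees one parameter fewer
  spz <- lst_model_spec("LST", 2, restriction = "none", fixed_zero_eps = 3L)
  expect_equal(27 - spz$npar, 12)
})

test_that("indicator-specific factor adds exactly one parameter", {
  s0 <- lst_model_spec("LS", 2, mi_level = "configural")
  s1 <- lst_model_spec("LS", 2, mi_level = "configural",
                       indicator_specific = 2L)
  expect_equal(s1$npar, s0$npar + 1)
  th <- stats::setNames(rep(0.5, s1$npar), s1$free_labels)
  th["var_is"] <- 0.3
  m <- implied_moments(s1, th)
  # the method factor raises only the covariances among indicator-2 variables
  m0 <- implied_moments(s0, th[s0$free_labels])
  d <- m$sigma - m0$sigma
  expect_equal(d[2, 4], 0.3)
  expect_equal(d[1, 3], 0)
})
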