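test_that("saturated FIML fit reproduces complete-data ML moments", {
  d <- simulate_latent_dataset(study_latent_params(200, seed = 13))
  sdat <- sem_data(d$data)
  sat <- fit_saturated(sdat)
  x <- as.matrix(d$data[, -1])
  mu <- colMeans(x)
  s_ml <- crossprod(sweep(x, 2, mu)) / nrow(x)
  expect_lt(max(abs(sat$mu - mu)), 1e-8)
  expect_lt(max(abs(sat$sigma - s_ml)), 1e-8)
})

test_that("LT chi-square matches an independent generic-optimizer computation", {
  # three small fixtures with different populations
  fixtures <- list(
    study_latent_params(120, seed = 301),
    latent_sim_params(150, trait_var = 1, state_residual_vars = 0.2,
                      error_vars = 0.3, slope_loadings = 0, seed = 302),
    latent_sim_params(100, trait_var = 2, state_residual_vars = c(0.5, 1, 1.5),
                      error_vars = 0.2, slope_loadings = 0, seed = 303))
  for (p in fixtures) {
    d <- simulate_latent_dataset(p)
    x <- as.matrix(d$data[, -1])
    spec <- lst_model_spec("LT", 2, restriction = "A")
    f <- fit_ml(spec, d$data, restarts = 3)
    # independent route: generic BFGS on a separately coded LT likelihood
    neg_ll <- function(par) {
      l <- c(1, par[1], par[2], par[2] * par[1], par[3], par[3] * par[1])
      sg <- par[4] * outer(l, l) + diag(par[5], 6)
      ch <- tryCatch(chol(sg), error = function(e) NULL)
      if (is.null(ch)) return(1e12)
      si <- chol2inv(ch)
      z <- sweep(x, 2, l * par[6])
      0.5 * (nrow(x) * (6 * log(2 * pi) + 2 * sum(log(diag(ch)))) +
               sum((z %*% si) * z))
    }
    o <- stats::optim(c(1, 1, 1, 1, 0.5, 0), neg_ll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    chi_oracle <- 2 * (fit_saturated(sem_data(d$data))$logLik + o$value)
    expect_equal(f$chisq, chi_oracle, tolerance = 1e-4)
  }
})

test_that("parameters are recovered within 3 SE at n = 2000", {
  d <- simulate_latent_dataset(study_latent_params(2000, seed = 17))
  f <- fit_ml(lst_model_spec("LST_T", 2, restriction = "C"), d$data,
              restarts = 2)
  expect_true(f$converged)
  truth <- c(var_t = 4, var_sr = 1.6, eps = 0.08, mu_t = 0)
  for (nm in names(truth)) {
    est <- f$theta[nm]
    se <- f$par_table$se[f$par_table$label == nm]
    expect_lt(abs(est - truth[nm]), 3 * se)
  }
})

test_that("FIML beats listwise deletion under 20% MCAR missingness", {
  reps <- 12
  err_fiml <- err_lw <- matrix(NA_real_, reps, 3)
  spec <- lst_model_spec("LST_T", 2, restriction = "C")
  truth <- c(var_t = 4, var_sr = 1.6, eps = 0.08)
  for (r in seq_len(reps)) {
    p <- study_latent_params(300, seed = 4000 + r, missing_rate = 0.2)
    d <- simulate_latent_dataset(p)
    ff <- fit_ml(spec, d$data, missing = "fiml", restarts = 1, se = FALSE,
                 chisq = FALSE)
    fl <- fit_ml(spec, d$data, missing = "listwise", restarts = 1, se = FALSE,
                 chisq = FALSE)
    err_fiml[r, ] <- ff$theta[names(truth)] - truth
    err_lw[r, ] <- fl$theta[names(truth)] - truth
  }
  rmse <- function(e) sqrt(mean(e^2))
  # overall RMSE across the variance parameters: FIML no worse
  expect_lt(rmse(err_fiml), rmse(err_lw) * 1.05)
})

test_that("likelihood is invariant to subject and indicator reordering", {
  d <- simulate_latent_dataset(study_latent_params(150, seed = 23))
  x <- as.matrix(d$data[, -1])
  spec <- lst_model_spec("LST_T", 2, restriction = "C")
  f1 <- fit_ml(spec, x, restarts = 1)
  # subjects shuffled
  f2 <- fit_ml(spec, x[sample.int(nrow(x)), ], restarts = 1)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-8)
  # indicators swapped within occasions (model symmetric under restriction C)
  perm <- c(2, 1, 4, 3, 6, 5)
  f3 <- fit_ml(spec, x[, perm], restarts = 1)
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-8)
})

test_that("adding constraints never increases the log-likelihood", {
  d <- simulate_latent_dataset(study_latent_params(250, seed = 29))
  lls <- sapply(c("none", "A", "B", "C"), function(r) {
    fit_ml(lst_model_spec("LST_T", 2, restriction = r), d$data,
           restarts = 2)$logLik
  })
  expect_true(all(diff(lls) <= 1e-6))
  # and the chi-square difference is nonnegative by construction
  f_full <- fit_ml(lst_model_spec("LST_T", 2, restriction = "none"), d$data,
                   restarts = 2)
  f_restr <- fit_ml(lst_model_spec("LST_T", 2, restriction = "C"), d$data,
                    restarts = 2)
  cmp <- chi2_difference(f_restr, f_full)
  expect_gte(cmp$dchisq, 0)
  expect_equal(cmp$ddf, 10)
})

test_that("the saturated model chi-square is zero and df counts are consistent", {
  d <- simulate_latent_dataset(study_latent_params(100, seed = 37))
  f <- fit_ml(lst_model_spec("LST", 2, restriction = "none"), d$data,
              restarts = 2)
  expect_equal(f$df, 27 - f$npar)
  expect_gte(f$chisq, 0)
  # identical model compared to itself: zero difference, p = 1
  f2 <- fit_ml(lst_model_spec("LST", 2, restriction = "A"), d$data,
               restarts = 2)
  cmp <- chi2_difference(f2, f)
  expect_error(chi2_difference(f, f2), "degrees of freedom")
})

test_that("negative variance estimates are reported, and the remedy refits with eps fixed to 0", {
  # population with a tiny error variance produces Heywood cases at small n
  found <- FALSE
  for (s in 1:12) {
    p <- latent_sim_params(60, trait_var = 4, state_residual_vars = 1.6,
                           error_vars = 0.005, slope_loadings = 0, seed = 600 + s)
    d <- simulate_latent_dataset(p)
    f <- fit_ml(lst_model_spec("LST_T", 2, restriction = "none"), d$data,
                restarts = 1, se = FALSE, chisq = FALSE)
    if (f$converged && any(grepl("^eps", f$neg_variances))) {
      found <- TRUE
      red <- reduce_family(d$data, "LST_T", restarts = 1)
      final_eps <- red$fit$params$eps
      expect_true(all(final_eps >= 0))
      break
    }
  }
  expect_true(found)
})
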