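#' Parameters for latent-level data simulation
#'
#' Defines the population model from which manifest indicator values are
#' drawn: a latent trait (optionally with a linear-change slope factor),
#' occasion-specific state residuals, and indicator-level measurement error:
#' `X_ik = intercept + lambda_ik * (gamma_i * T + sigma_i * SL + SR_i) +
#' e_ik`.
#'
#' @param n_subjects Number of subjects.
#' @param n_occasions Number of measurement occasions (default 3).
#' @param n_indicators Indicators (test sets) per occasion, 2-4.
#' @param trait_mean,trait_var Mean and variance of the latent trait T.
#' @param state_residual_vars Variance of the state residual SR_i per
#'   occasion (recycled).
#' @param error_vars Measurement error variance per indicator-occasion:
#'   scalar, per-occasion vector, or occasions x indicators matrix.
#' @param state_loadings Loadings lambda_ik of indicators on states
#'   (occasions x indicators matrix or scalar, default 1).
#' @param trait_loadings Loadings gamma_i of states on the trait (per
#'   occasion, default 1).
#' @param slope_mean,slope_var,trait_slope_cov Slope factor moments (slope
#'   off when `slope_var = 0` and `slope_mean = 0`).
#' @param slope_loadings Slope loadings sigma_i per occasion (default
#'   `0, 1, 2, ...`: linear change).
#' @param intercept Common manifest intercept.
#' @param missing_rate MCAR missingness proportion in `[0, 1)`.
#' @param seed Integer seed.
#' @return Validated parameter list of class `latent_sim_params`.
#' @export
latent_sim_params <- function(n_subjects,
                              n_occasions = 3,
                              n_indicators = 2,
                              trait_mean = 0,
                              trait_var = 1,
                              state_residual_vars = 0.4,
                              error_vars = 0.1,
                              state_loadings = 1,
                              trait_loadings = 1,
                              slope_mean = 0,
                              slope_var = 0,
                              trait_slope_cov = 0,
                              slope_loadings = seq_len(n_occasions) - 1,
                              intercept = 0,
                              missing_rate = 0,
                              seed = 1L) {
  if (!n_indicators %in% 2:4) stop("`n_indicators` must be 2-4", call. = FALSE)
  p <- list(
    n_subjects = as.integer(n_subjects),
    n_occasions = as.integer(n_occasions),
    n_indicators = as.integer(n_indicators),
    trait_mean = trait_mean,
    trait_var = trait_var,
    state_residual_vars = rep_len(state_residual_vars, n_occasions),
    error_vars = expand_eps(error_vars, n_occasions, n_indicators),
    state_loadings = expand_mat(state_loadings, n_occasions, n_indicators),
    trait_loadings = rep_len(trait_loadings, n_occasions),
    slope_mean = slope_mean,
    slope_var = slope_var,
    trait_slope_cov = trait_slope_cov,
    slope_loadings = rep_len(slope_loadings, n_occasions),
    intercept = intercept,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (p$trait_var < 0 || p$slope_var < 0 || any(p$state_residual_vars < 0) ||
      any(p$error_vars < 0)) {
    stop("all variances must be >= 0", call. = FALSE)
  }
  if (abs(p$trait_slope_cov) > sqrt(p$trait_var * p$slope_var) + 1e-12) {
    stop("|trait_slope_cov| must not exceed sqrt(trait_var * slope_var)",
         call. = FALSE)
  }
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  class(p) <- "latent_sim_params"
  p
}

expand_eps <- function(x, i, k) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == i, ncol(x) == k)
    return(x)
  }
  if (length(x) == i) return(matrix(rep(x, k), i, k))
  matrix(rep_len(x, i * k), i, k)
}

expand_mat <- function(x, i, k) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == i, ncol(x) == k)
    return(x)
  }
  matrix(rep_len(x, i * k), i, k)
}

#' Population moments and variance shares of a simulation design
#'
#' Model-implied mean vector, covariance matrix, and the population
#' consistency / occasion-specificity / reliability per indicator-occasion
#' for a [latent_sim_params] design. Used as ground truth in recovery tests.
#'
#' @param params A [latent_sim_params] object.
#' @return List with `mu`, `sigma`, and a data frame `shares` (columns
#'   `occasion`, `indicator`, `con`, `spe`, `rel`).
#' @export
latent_population_moments <- function(params) {
  i_n <- params$n_occasions
  k_n <- params$n_indicators
  ga <- params$trait_loadings
  sg <- params$slope_loadings
  phi_s <- outer(ga, ga) * params$trait_var +
    outer(sg, sg) * params$slope_var +
    (outer(ga, sg) + outer(sg, ga)) * params$trait_slope_cov +
    diag(params$state_residual_vars, i_n)
  p <- i_n * k_n
  b <- matrix(0, p, i_n)
  for (i in seq_len(i_n)) {
    for (k in seq_len(k_n)) {
      b[(i - 1) * k_n + k, i] <- params$state_loadings[i, k]
    }
  }
  sigma <- b %*% phi_s %*% t(b) + diag(as.vector(t(params$error_vars)), p)
  m_s <- ga * params$trait_mean + sg * params$slope_mean
  mu <- params$intercept + drop(b %*% m_s)

  shares <- expand.grid(indicator = seq_len(k_n), occasion = seq_len(i_n))
  shares <- shares[, c("occasion", "indicator")]
  con <- spe <- numeric(nrow(shares))
  for (r in seq_len(nrow(shares))) {
    i <- shares$occasion[r]; k <- shares$indicator[r]
    la2 <- params$state_loadings[i, k]^2
    vx <- sigma[(i - 1) * k_n + k, (i - 1) * k_n + k]
    con[r] <- la2 * (ga[i]^2 * params$trait_var + sg[i]^2 * params$slope_var +
                       2 * ga[i] * sg[i] * params$trait_slope_cov) / vx
    spe[r] <- la2 * params$state_residual_vars[i] / vx
  }
  shares$con <- con
  shares$spe <- spe
  shares$rel <- con + spe
  list(mu = mu, sigma = sigma, shares = shares)
}

#' Simulate a latent-level manifest dataset
#'
#' Draws subject-level trait (and slope) scores, occasion-level state
#' residuals and indicator-level errors, assembles the manifest variables,
#' and applies MCAR missingness. The latent draws are returned alongside the
#' data so downstream estimates can be checked against ground truth.
#'
#' @param params A [latent_sim_params] object.
#' @return List with `data` (wide data frame: `subject`, then columns
#'   `x<occasion>_<indicator>` in occasion-major order) and `truth` (data
#'   frame of the latent draws per subject).
#' @export
simulate_latent_dataset <- function(params) {
  stopifnot(inherits(params, "latent_sim_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  i_n <- params$n_occasions
  k_n <- params$n_indicators

  cov_ts <- matrix(c(params$trait_var, params$trait_slope_cov,
                     params$trait_slope_cov, params$slope_var), 2, 2)
  ev <- eigen(cov_ts, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("trait/slope covariance matrix is not positive semi-definite",
         call. = FALSE)
  }
  ch <- chol(cov_ts + diag(1e-12, 2))
  ts <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
  trait <- ts[, 1] + params$trait_mean
  slope <- ts[, 2] + params$slope_mean

  sr <- sapply(seq_len(i_n), function(i) {
    stats::rnorm(n, 0, sqrt(params$state_residual_vars[i]))
  })
  if (n == 1) sr <- matrix(sr, 1, i_n)

  p <- i_n * k_n
  x <- matrix(NA_real_, n, p)
  cn <- character(p)
  for (i in seq_len(i_n)) {
    state <- params$trait_loadings[i] * trait +
      params$slope_loadings[i] * slope + sr[, i]
    for (k in seq_len(k_n)) {
      col <- (i - 1) * k_n + k
      x[, col] <- params$intercept + params$state_loadings[i, k] * state +
        stats::rnorm(n, 0, sqrt(params$error_vars[i, k]))
      cn[col] <- sprintf("x%d_%d", i, k)
    }
  }
  if (params$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(n * p) < params$missing_rate, n, p)
    x[drop_mask] <- NA_real_
  }
  colnames(x) <- cn
  truth <- data.frame(subject = seq_len(n), trait = trait, slope = slope)
  for (i in seq_len(i_n)) truth[[sprintf("sr%d", i)]] <- sr[, i]
  list(data = data.frame(subject = seq_len(n), x), truth = truth)
}
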