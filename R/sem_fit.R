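#' Prepare a dataset for full-information ML estimation
#'
#' Groups rows by missing-data pattern and precomputes per-pattern sufficient
#' statistics, so every likelihood evaluation costs one pass over patterns
#' rather than over cases. Saturated- and baseline-model log-likelihoods are
#' computed lazily and cached.
#'
#' @param x Matrix or data frame of manifest variables (a `subject` column is
#'   dropped if present). Rows without a single observed value are removed.
#' @return Object of class `sem_data`.
#' @export
sem_data <- function(x) {
  if (inherits(x, "sem_data")) return(x)
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "subject"), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  keep <- rowSums(!is.na(x)) > 0
  x <- x[keep, , drop = FALSE]
  obs <- !is.na(x)
  pid <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- lapply(unique(pid), function(id) {
    rows <- which(pid == id)
    vars <- which(obs[rows[1], ])
    sub <- x[rows, vars, drop = FALSE]
    m <- colMeans(sub)
    w <- if (length(rows) > 1) crossprod(sweep(sub, 2, m)) else
      matrix(0, length(vars), length(vars))
    list(vars = vars, n = length(rows), mean = m, scatter = w, rows = rows)
  })
  env <- new.env(parent = emptyenv())
  structure(list(x = x, n = nrow(x), p = ncol(x), patterns = patterns,
                 complete = all(obs), cache = env),
            class = "sem_data")
}

#' @export
print.sem_data <- function(x, ...) {
  cat(sprintf("<sem_data> %d cases x %d variables, %d missing pattern(s)\n",
              x$n, x$p, length(x$patterns)))
  invisible(x)
}

LOG2PI <- log(2 * pi)

# total observed-data log-likelihood under N(mu, Sigma); NA if Sigma (or an
# observed submatrix) is not positive definite
fiml_loglik <- function(mu, sigma, sd) {
  ll <- 0
  for (g in sd$patterns) {
    v <- g$vars
    ch <- tryCatch(chol(sigma[v, v, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    logdet <- 2 * sum(log(diag(ch)))
    sinv <- chol2inv(ch)
    d <- g$mean - mu[v]
    q <- sum(sinv * g$scatter) + g$n * drop(crossprod(d, sinv %*% d))
    ll <- ll - 0.5 * (g$n * (length(v) * LOG2PI + logdet) + q)
  }
  ll
}

# per-case log-likelihood vector (same model), for score computation
casewise_loglik <- function(mu, sigma, sd) {
  out <- numeric(sd$n)
  for (g in sd$patterns) {
    v <- g$vars
    ch <- tryCatch(chol(sigma[v, v, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(rep(NA_real_, sd$n))
    logdet <- 2 * sum(log(diag(ch)))
    sinv <- chol2inv(ch)
    z <- sweep(sd$x[g$rows, v, drop = FALSE], 2, mu[v])
    q <- rowSums((z %*% sinv) * z)
    out[g$rows] <- -0.5 * (length(v) * LOG2PI + logdet + q)
  }
  out
}

# --- saturated (unstructured) model -----------------------------------------

# theta: p means, p log-chol-diagonals, p(p-1)/2 sub-diagonal chol entries
sat_unpack <- function(theta, p) {
  mu <- theta[seq_len(p)]
  l <- matrix(0, p, p)
  diag(l) <- exp(theta[p + seq_len(p)])
  if (p > 1) l[lower.tri(l)] <- theta[-seq_len(2 * p)]
  list(mu = mu, sigma = tcrossprod(l))
}

#' Saturated and baseline log-likelihoods under FIML
#'
#' The saturated model (free mean vector and unstructured covariance) is
#' fitted by direct maximization of the observed-data likelihood; for
#' complete data the closed-form ML moments are used. The baseline
#' (independence) model frees every mean and variance but fixes covariances
#' to zero, which under MCAR factorizes into per-variable univariate fits.
#'
#' @param sd A [sem_data] object.
#' @return `fit_saturated`: list with `logLik`, `mu`, `sigma`, `npar`;
#'   `fit_baseline`: list with `logLik`, `npar`.
#' @export
fit_saturated <- function(sd) {
  sd <- sem_data(sd)
  if (!is.null(sd$cache$saturated)) return(sd$cache$saturated)
  p <- sd$p
  if (sd$complete) {
    mu <- colMeans(sd$x)
    sc <- crossprod(sweep(sd$x, 2, mu)) / sd$n
    ll <- fiml_loglik(mu, sc, sd)
    out <- list(logLik = ll, mu = mu, sigma = sc,
                npar = p + p * (p + 1) / 2, converged = TRUE)
  } else {
    start <- start_moments(sd)
    l0 <- t(chol(start$sigma))
    th0 <- c(start$mu, log(diag(l0)), l0[lower.tri(l0)])
    obj <- function(th) {
      m <- sat_unpack(th, p)
      ll <- fiml_loglik(m$mu, m$sigma, sd)
      if (is.na(ll)) 1e12 else -ll
    }
    opt <- stats::nlminb(th0, obj, control = list(iter.max = 2000,
                                                  eval.max = 4000))
    m <- sat_unpack(opt$par, p)
    out <- list(logLik = -opt$objective, mu = m$mu, sigma = m$sigma,
                npar = p + p * (p + 1) / 2,
                converged = opt$convergence == 0)
  }
  sd$cache$saturated <- out
  out
}

#' @rdname fit_saturated
#' @export
fit_baseline <- function(sd) {
  sd <- sem_data(sd)
  if (!is.null(sd$cache$baseline)) return(sd$cache$baseline)
  ll <- 0
  for (j in seq_len(sd$p)) {
    v <- sd$x[, j]
    v <- v[!is.na(v)]
    s2 <- mean((v - mean(v))^2)
    ll <- ll - 0.5 * length(v) * (LOG2PI + log(s2) + 1)
  }
  out <- list(logLik = ll, npar = 2 * sd$p)
  sd$cache$baseline <- out
  out
}

# available-case means and positive-definite pairwise covariance start
start_moments <- function(sd) {
  x <- sd$x
  mu <- colMeans(x, na.rm = TRUE)
  s <- stats::cov(x, use = "pairwise.complete.obs")
  s[is.na(s)] <- 0
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  floor_ev <- max(1e-6 * mean(diag(s)), 1e-8)
  vals <- pmax(e$values, floor_ev)
  list(mu = mu, sigma = e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors))
}

# --- model fitting ----------------------------------------------------------

# moment-based start values for a model spec
start_values <- function(spec, sd) {
  sm <- start_moments(sd)
  s <- sm$sigma
  i_n <- spec$n_occasions
  k_n <- spec$n_indicators
  occ_of <- rep(seq_len(i_n), each = k_n)
  v_bar <- mean(diag(s))
  off <- which(upper.tri(s), arr.ind = TRUE)
  cross <- mean(s[off][occ_of[off[, 1]] != occ_of[off[, 2]]])
  within <- if (k_n > 1) mean(s[off][occ_of[off[, 1]] == occ_of[off[, 2]]]) else
    0.7 * v_bar
  if (!is.finite(cross)) cross <- 0.3 * v_bar
  var_t0 <- max(cross, 0.1 * v_bar)
  var_sr0 <- max(within - cross, 0.05 * v_bar)
  eps0 <- max(v_bar - within, 0.05 * v_bar)
  occ_mean <- tapply(sm$mu, occ_of, mean)

  th <- numeric(spec$npar)
  names(th) <- spec$free_labels
  for (lab in spec$free_labels) {
    row <- spec$ptab[match(lab, spec$ptab$label), ]
    th[lab] <- switch(row$mat,
      lambda = 1,
      gamma = 1,
      eps = eps0,
      var_sr = var_sr0,
      var_t = var_t0,
      mu_t = mean(sm$mu),
      mu_sl = 0,
      var_sl = 0.1 * v_bar,
      cov_tsl = 0,
      sigma = 2,
      s_int = occ_mean[row$i],
      s_mean = occ_mean[row$i],
      nu = sm$mu[(row$i - 1) * k_n + row$k] - occ_mean[row$i],
      phi = if (row$i == row$k) within else cross,
      var_is = 0.05 * v_bar,
      0)
  }
  th
}

#' Fit a latent state-trait model by (full-information) maximum likelihood
#'
#' Maximizes the case-wise Gaussian log-likelihood over each case's observed
#' pattern (`missing = "fiml"`) or over complete rows only
#' (`missing = "listwise"`). Several starts are used: one moment-based start
#' plus deterministic jittered restarts; the best converged solution is kept.
#' Variances are estimated unconstrained, so Heywood cases (negative variance
#' estimates) are visible in the output rather than silently truncated.
#'
#' @param spec An [lst_model_spec].
#' @param data Matrix/data frame of manifest variables or a [sem_data]
#'   object. Columns named `x<i>_<k>` are reordered canonically; otherwise
#'   column order is taken as occasion-major.
#' @param missing `"fiml"` or `"listwise"`.
#' @param restarts Total number of starts (>= 1).
#' @param se Compute naive (observed-information) standard errors.
#' @param chisq Compute the chi-square against the saturated model (under
#'   missing data the saturated model requires its own optimization; recovery
#'   simulations that only need parameter estimates can skip it).
#' @param grad_tol Maximum absolute score at the optimum for the fit to count
#'   as converged.
#' @return Object of class `lst_fit`: parameter table, log-likelihood,
#'   chi-square against the saturated model, naive standard errors, implied
#'   moments, convergence diagnostics, and the names of any negative variance
#'   estimates.
#' @export
fit_ml <- function(spec, data, missing = c("fiml", "listwise"),
                   restarts = 5, se = TRUE, chisq = TRUE, grad_tol = 1e-2) {
  missing <- match.arg(missing)
  stopifnot(inherits(spec, "lst_model_spec"))
  if (!inherits(data, "sem_data")) {
    if (is.data.frame(data)) data <- data[, setdiff(names(data), "subject"), drop = FALSE]
    data <- as.matrix(data)
    want <- manifest_names(spec$n_occasions, spec$n_indicators)
    if (!is.null(colnames(data)) && all(want %in% colnames(data))) {
      data <- data[, want, drop = FALSE]
    }
    if (missing == "listwise") data <- data[stats::complete.cases(data), , drop = FALSE]
    data <- sem_data(data)
  }
  sd <- data
  if (sd$p != spec$p) {
    stop(sprintf("data has %d columns but the model implies %d manifest variables",
                 sd$p, spec$p), call. = FALSE)
  }
  if (sd$n < 2) stop("need at least 2 cases", call. = FALSE)

  obj <- function(th) {
    m <- implied_moments(spec, th)
    ll <- fiml_loglik(m$mu, m$sigma, sd)
    if (is.na(ll)) 1e12 else -ll
  }

  th0 <- start_values(spec, sd)
  starts <- list(th0)
  if (restarts > 1) {
    rs <- get_rng_state()
    on.exit(set_rng_state(rs), add = TRUE)
    set.seed(20231101L)
    for (r in seq_len(restarts - 1)) {
      starts[[r + 1L]] <- th0 * stats::runif(length(th0), 0.6, 1.5) +
        stats::rnorm(length(th0), 0, 0.05 * (abs(th0) + 0.1))
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, obj, control = list(iter.max = 1000,
                                                 eval.max = 2000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  theta <- best$par
  names(theta) <- spec$free_labels
  ll <- -best$objective
  grad <- num_grad(obj, theta)
  converged <- best$convergence == 0 && max(abs(grad)) < grad_tol * max(1, abs(ll))

  vc <- NULL
  se_v <- rep(NA_real_, spec$npar)
  if (se && spec$npar > 0) {
    h <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
    if (!is.null(h)) {
      vc <- tryCatch(solve(h), error = function(e) NULL)
      if (!is.null(vc)) {
        dg <- diag(vc)
        se_v <- rep(NA_real_, length(dg))
        se_v[dg > 0] <- sqrt(dg[dg > 0])
      }
    }
  }

  n_moments <- sd$p + sd$p * (sd$p + 1) / 2
  df <- n_moments - spec$npar
  df_b <- n_moments - 2 * sd$p
  if (chisq) {
    sat <- fit_saturated(sd)
    base <- fit_baseline(sd)
    chisq_v <- max(2 * (sat$logLik - ll), 0)
    chisq_b <- max(2 * (sat$logLik - base$logLik), 0)
    sat_ll <- sat$logLik
  } else {
    chisq_v <- NA_real_
    chisq_b <- NA_real_
    sat_ll <- NA_real_
  }

  st_par <- assemble_params(spec, theta)
  var_rows <- spec$ptab$mat %in% c("var_t", "var_sr", "eps", "var_sl", "var_is") |
    (spec$ptab$mat == "phi" & spec$ptab$i == spec$ptab$k)
  est_full <- spec$ptab$value
  est_full[spec$ptab$free] <- theta[match(spec$ptab$label[spec$ptab$free],
                                          spec$free_labels)]
  neg <- unique(spec$ptab$label[var_rows & spec$ptab$free & est_full < 0])

  par_table <- data.frame(label = spec$free_labels, estimate = unname(theta),
                          se = se_v)
  structure(
    list(spec = spec, theta = theta, par_table = par_table,
         params = st_par, logLik = ll, npar = spec$npar, n = sd$n,
         chisq = chisq_v, df = df,
         p_value = if (df > 0 && !is.na(chisq_v))
           stats::pchisq(chisq_v, df, lower.tail = FALSE) else NA_real_,
         sat_logLik = sat_ll, baseline_chisq = chisq_b, baseline_df = df_b,
         implied = implied_from_params(spec, st_par),
         vcov = vc, converged = converged, max_grad = max(abs(grad)),
         neg_variances = neg, missing = missing, data = sd,
         scaling = NULL, chisq_scaled = NULL, se_robust = NULL),
    class = "lst_fit")
}

#' @export
print.lst_fit <- function(x, ...) {
  lvl <- if (x$spec$family == "LS") x$spec$mi_level else x$spec$restriction
  cat(sprintf("<lst_fit> %s (%s), n = %d, logLik = %.3f\n",
              x$spec$family, lvl, x$n, x$logLik))
  cat(sprintf("  chi-square %.3f on %d df (p = %.4g)%s\n", x$chisq, x$df,
              x$p_value,
              if (!is.null(x$chisq_scaled))
                sprintf("; scaled %.3f (c = %.3f)", x$chisq_scaled, x$scaling)
              else ""))
  if (!x$converged) cat("  WARNING: not converged (max |score| ",
                        format(x$max_grad), ")\n", sep = "")
  if (length(x$neg_variances)) {
    cat("  negative variance estimate(s): ",
        paste(x$neg_variances, collapse = ", "), "\n", sep = "")
  }
  print(x$par_table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
logLik.lst_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
coef.lst_fit <- function(object, ...) object$theta

num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hj <- h * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    g[j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  g
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

set_rng_state <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", s, envir = globalenv())
  }
}
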