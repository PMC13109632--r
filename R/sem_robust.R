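#' Robust (sandwich) standard errors and scaled test statistics
#'
#' Adds to a fitted model: Huber-White sandwich standard errors
#' (observed-information bread, casewise score outer-product meat) and the
#' mean-corrected scaled chi-square with its scaling factor, computed from
#' the normal-theory residual weight matrix and the fourth-order moments of
#' the data. The independence-baseline statistic is scaled with the same
#' machinery so scaled CFI values are available.
#'
#' The scaling factor uses complete cases for the fourth-moment matrix; with
#' heavy missingness it degrades gracefully to the unscaled statistic (with
#' a warning) when too few complete cases remain.
#'
#' @param fit An [lst_fit].
#' @return The fit with `se_robust`, `vcov_robust`, `scaling`,
#'   `chisq_scaled`, `p_scaled`, `baseline_chisq_scaled` filled in.
#' @export
robust_correction <- function(fit) {
  stopifnot(inherits(fit, "lst_fit"))
  sd <- fit$data
  spec <- fit$spec
  theta <- fit$theta
  q <- length(theta)

  # sandwich: A^-1 B A^-1 with A = observed information, B = sum of score
  # outer products (scores by central differences of the casewise loglik)
  obj <- function(th) {
    m <- implied_moments(spec, th)
    ll <- fiml_loglik(m$mu, m$sigma, sd)
    if (is.na(ll)) 1e12 else -ll
  }
  a <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  scores <- matrix(NA_real_, sd$n, q)
  for (j in seq_len(q)) {
    h <- 1e-5 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    mp <- implied_moments(spec, tp)
    mm <- implied_moments(spec, tm)
    scores[, j] <- (casewise_loglik(mp$mu, mp$sigma, sd) -
                      casewise_loglik(mm$mu, mm$sigma, sd)) / (2 * h)
  }
  fit$vcov_robust <- NULL
  fit$se_robust <- rep(NA_real_, q)
  if (!is.null(a)) {
    ainv <- tryCatch(solve(a), error = function(e) NULL)
    if (!is.null(ainv) && !anyNA(scores)) {
      b <- crossprod(scores)
      vr <- ainv %*% b %*% ainv
      fit$vcov_robust <- vr
      dg <- diag(vr)
      ser <- rep(NA_real_, length(dg))
      ser[dg > 0] <- sqrt(dg[dg > 0])
      fit$se_robust <- ser
      fit$par_table$se_robust <- fit$se_robust
    }
  }

  # scaling factor c = tr(U Gamma) / df
  comp <- sd$x[stats::complete.cases(sd$x), , drop = FALSE]
  p <- sd$p
  if (nrow(comp) < p + 2 || fit$df <= 0) {
    warning("too few complete cases (or df = 0); scaled statistics unavailable")
    fit$scaling <- NA_real_
    fit$chisq_scaled <- fit$chisq
    fit$p_scaled <- fit$p_value
    return(fit)
  }
  gam <- fourth_moment_gamma(comp)
  w <- nt_weight_matrix(fit$implied$sigma)
  delta <- moment_jacobian(spec, theta)
  wd <- w %*% delta
  u <- w - wd %*% solve(crossprod(delta, wd), t(wd))
  cc <- sum(u * gam) / fit$df
  if (!is.finite(cc) || cc <= 0) {
    warning("nonpositive scaling factor; falling back to unscaled statistic")
    fit$scaling <- NA_real_
    fit$chisq_scaled <- fit$chisq
    fit$p_scaled <- fit$p_value
  } else {
    fit$scaling <- cc
    fit$chisq_scaled <- fit$chisq / cc
    fit$p_scaled <- stats::pchisq(fit$chisq_scaled, fit$df, lower.tail = FALSE)
  }

  # baseline scaling (independence model): jacobian columns are unit vectors
  # for each mean and each diagonal vech position
  base <- fit_baseline(sd)
  db <- baseline_jacobian(p)
  mu_b <- colMeans(comp)
  var_b <- apply(comp, 2, function(v) mean((v - mean(v))^2))
  wb <- nt_weight_matrix(diag(var_b, p))
  wdb <- wb %*% db
  ub <- wb - wdb %*% solve(crossprod(db, wdb), t(wdb))
  ccb <- sum(ub * gam) / fit$baseline_df
  fit$baseline_chisq_scaled <- if (is.finite(ccb) && ccb > 0)
    fit$baseline_chisq / ccb else fit$baseline_chisq
  fit
}

# Gamma: asymptotic covariance of (xbar, vech(S)) from empirical fourth
# moments of complete cases
fourth_moment_gamma <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  mu <- colMeans(x)
  z <- sweep(x, 2, mu)
  s <- crossprod(z) / n
  idx <- vech_index(p)
  d <- matrix(0, n, p + nrow(idx))
  d[, seq_len(p)] <- z
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    d[, p + r] <- z[, i] * z[, j] - s[i, j]
  }
  crossprod(d) / n
}

# normal-theory ML weight matrix for moments (mu, vech(Sigma))
nt_weight_matrix <- function(sigma) {
  p <- ncol(sigma)
  sinv <- solve(sigma)
  dmat <- dup_matrix(p)
  ws <- 0.5 * t(dmat) %*% (sinv %x% sinv) %*% dmat
  nv <- nrow(vech_index(p))
  w <- matrix(0, p + nv, p + nv)
  w[seq_len(p), seq_len(p)] <- sinv
  w[p + seq_len(nv), p + seq_len(nv)] <- ws
  w
}

# numerical jacobian of (mu(theta), vech(Sigma(theta)))
moment_jacobian <- function(spec, theta) {
  p <- spec$p
  idx <- vech_index(p)
  mfun <- function(th) {
    m <- implied_moments(spec, th)
    c(m$mu, m$sigma[idx])
  }
  f0 <- mfun(theta)
  jac <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-6 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    jac[, j] <- (mfun(tp) - mfun(tm)) / (2 * h)
  }
  jac
}

baseline_jacobian <- function(p) {
  idx <- vech_index(p)
  nv <- nrow(idx)
  d <- matrix(0, p + nv, 2 * p)
  d[seq_len(p), seq_len(p)] <- diag(p)
  for (r in seq_len(nv)) {
    if (idx[r, 1] == idx[r, 2]) d[p + r, p + idx[r, 1]] <- 1
  }
  d
}

# lower-triangle (column-major) index pairs, diagonal included
vech_index <- function(p) {
  out <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  out[order(out[, 2], out[, 1]), , drop = FALSE]
}

dup_matrix <- function(p) {
  idx <- vech_index(p)
  nv <- nrow(idx)
  d <- matrix(0, p * p, nv)
  for (r in seq_len(nv)) {
    i <- idx[r, 1]; j <- idx[r, 2]
    d[(j - 1) * p + i, r] <- 1
    d[(i - 1) * p + j, r] <- 1
  }
  d
}

#' Chi-square difference test between nested models
#'
#' Likelihood-ratio test of a restricted model against a fuller model fitted
#' to the same data, optionally with the Satorra-Bentler scaled difference
#' using `c_d = (d0*c0 - d1*c1)/(d0 - d1)`. A nonpositive `c_d` (a known
#' pathology of the scaled test) falls back to the unscaled statistic with a
#' warning. When both fits carry baseline statistics the CFI change is
#' reported alongside.
#'
#' @param restricted,full [lst_fit] objects; `restricted` must have more df.
#' @param scaled Use scaled statistics (both fits need
#'   [robust_correction()]).
#' @return List with `dchisq`, `ddf`, `p_value`, `delta_cfi`, `scaled`,
#'   `c_d`.
#' @export
chi2_difference <- function(restricted, full, scaled = FALSE) {
  d0 <- restricted$df
  d1 <- full$df
  if (d0 <= d1) {
    stop("`restricted` must have more degrees of freedom than `full`",
         call. = FALSE)
  }
  ddf <- d0 - d1
  t0 <- restricted$chisq
  t1 <- full$chisq
  stat <- t0 - t1
  c_d <- NA_real_
  if (scaled) {
    c0 <- restricted$scaling
    c1 <- full$scaling
    if (is.null(c0) || is.null(c1) || is.na(c0) || is.na(c1)) {
      stop("scaled difference requested but scaling factors missing",
           call. = FALSE)
    }
    c_d <- (d0 * c0 - d1 * c1) / ddf
    if (!is.finite(c_d) || c_d <= 0) {
      warning("nonpositive difference-test scaling factor; using unscaled statistic")
      scaled <- FALSE
    } else {
      stat <- (t0 - t1) / c_d
    }
  }
  stat <- max(stat, 0)
  cfi_of <- function(f) {
    num <- max(f$chisq - f$df, 0)
    den <- max(f$baseline_chisq - f$baseline_df, num, 0)
    if (den == 0) 1 else 1 - num / den
  }
  list(dchisq = stat, ddf = ddf,
       p_value = stats::pchisq(stat, ddf, lower.tail = FALSE),
       delta_cfi = cfi_of(full) - cfi_of(restricted),
       scaled = scaled, c_d = c_d)
}

#' Critical ratios (z statistics) of the free parameters
#'
#' Estimate divided by standard error, with a two-sided normal p-value.
#' Robust standard errors are used when present.
#'
#' @param fit An [lst_fit].
#' @param robust Use sandwich standard errors (default: if available).
#' @return Data frame with `label`, `estimate`, `se`, `cr`, `p_value`.
#' @export
critical_ratios <- function(fit, robust = !is.null(fit$se_robust) &&
                              !all(is.na(fit$se_robust))) {
  se <- if (robust) fit$se_robust else fit$par_table$se
  cr <- ifelse(is.na(se) | se <= 0, NA_real_, fit$par_table$estimate / se)
  data.frame(label = fit$par_table$label,
             estimate = fit$par_table$estimate,
             se = se, cr = cr,
             p_value = 2 * stats::pnorm(-abs(cr)))
}

#' Mardia's test of multivariate normality
#'
#' Multivariate skewness `b1p` and kurtosis `b2p` on the complete-case
#' submatrix, with the asymptotic chi-square (skewness) and standard normal
#' (kurtosis) reference distributions.
#'
#' @param x Matrix or data frame of manifest variables.
#' @return List of class `mardia_test`: `b1p`, `skew_stat`, `skew_df`,
#'   `skew_p`, `b2p`, `kurt_z`, `kurt_p`, `n`, `p`, and `normal`
#'   (TRUE when neither test rejects at the 5% level).
#' @export
mardia_test <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, setdiff(names(x), "subject"), drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more complete cases than variables", call. = FALSE)
  mu <- colMeans(x)
  z <- sweep(x, 2, mu)
  s <- crossprod(z) / n
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch)) stop("singular covariance matrix", call. = FALSE)
  w <- z %*% backsolve(ch, diag(p))      # whitened: w w' = z S^-1 z'
  # b1p = sum over third-moment tensor squared: avoids the n x n matrix
  b1 <- 0
  for (a in seq_len(p)) for (b in seq_len(p)) for (cc in seq_len(p)) {
    b1 <- b1 + mean(w[, a] * w[, b] * w[, cc])^2
  }
  d2 <- rowSums(w^2)
  b2 <- mean(d2^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  skew_p <- stats::pchisq(skew_stat, skew_df, lower.tail = FALSE)
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  kurt_p <- 2 * stats::pnorm(-abs(kurt_z))
  structure(list(b1p = b1, skew_stat = skew_stat, skew_df = skew_df,
                 skew_p = skew_p, b2p = b2, kurt_z = kurt_z, kurt_p = kurt_p,
                 n = n, p = p, normal = skew_p >= 0.05 && kurt_p >= 0.05),
            class = "mardia_test")
}

#' @export
print.mardia_test <- function(x, ...) {
  cat(sprintf("Mardia test (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  skewness b1p = %.4f, chi2(%d) = %.2f, p = %.4g\n",
              x$b1p, x$skew_df, x$skew_stat, x$skew_p))
  cat(sprintf("  kurtosis b2p = %.4f, z = %.2f, p = %.4g\n",
              x$b2p, x$kurt_z, x$kurt_p))
  cat(if (x$normal) "  multivariate normality not rejected\n" else
    "  multivariate normality rejected\n")
  invisible(x)
}
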