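#' Fit indices for a fitted model
#'
#' CFI against the independence baseline, RMSEA with a noncentral chi-square
#' confidence interval and closeness test, and SRMR over standardized
#' residual covariances and means.
#'
#' Conventions: RMSEA uses `n = N` by default (`n_minus_one = TRUE` switches
#' to `N - 1`); the confidence level defaults to 0.90 with 0.95 available;
#' the closeness-test null RMSEA defaults to 0.05.
#'
#' @param fit An [lst_fit].
#' @param scaled Use the scaled chi-square statistics if present (see
#'   [robust_correction()]).
#' @param ci_level Confidence level of the RMSEA interval.
#' @param rmsea_null Null RMSEA of the closeness test.
#' @param n_minus_one Use `N - 1` instead of `N` in the RMSEA denominator.
#' @return List of class `fit_indices`: `cfi`, `rmsea`, `rmsea_ci_lower`,
#'   `rmsea_ci_upper`, `rmsea_pclose`, `srmr`, plus the chi-square inputs.
#'   `df = 0` models get `NA` sentinels for CFI/RMSEA.
#' @export
fit_indices <- function(fit, scaled = FALSE, ci_level = 0.90,
                        rmsea_null = 0.05, n_minus_one = FALSE) {
  stopifnot(inherits(fit, "lst_fit"))
  if (scaled && is.null(fit$chisq_scaled)) {
    stop("no scaled statistics present; run robust_correction() first",
         call. = FALSE)
  }
  chisq <- if (scaled) fit$chisq_scaled else fit$chisq
  df <- fit$df
  chisq_b <- if (scaled && !is.null(fit$baseline_chisq_scaled))
    fit$baseline_chisq_scaled else fit$baseline_chisq
  df_b <- fit$baseline_df
  n <- fit$n - as.integer(n_minus_one)

  if (df <= 0) {
    cfi <- NA_real_
    rmsea <- lo <- hi <- pclose <- NA_real_
  } else {
    num <- max(chisq - df, 0)
    den <- max(chisq_b - df_b, chisq - df, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    rmsea <- sqrt(num / (df * n))
    ci <- rmsea_ci(chisq, df, n, ci_level)
    lo <- ci[1]; hi <- ci[2]
    pclose <- stats::pchisq(chisq, df, ncp = n * df * rmsea_null^2,
                            lower.tail = FALSE)
  }
  srmr <- srmr_value(fit)
  structure(list(cfi = cfi, rmsea = rmsea, rmsea_ci_lower = lo,
                 rmsea_ci_upper = hi, rmsea_pclose = pclose, srmr = srmr,
                 chisq = chisq, df = df, ci_level = ci_level,
                 scaled = scaled),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("CFI %.3f | RMSEA %.3f (%g%% CI %.3f-%.3f, pclose %.3f) | SRMR %.3f%s\n",
              x$cfi, x$rmsea, 100 * x$ci_level, x$rmsea_ci_lower,
              x$rmsea_ci_upper, x$rmsea_pclose, x$srmr,
              if (x$scaled) " [scaled]" else ""))
  invisible(x)
}

# RMSEA interval by inverting the noncentral chi-square distribution
rmsea_ci <- function(chisq, df, n, level = 0.90) {
  a <- (1 - level) / 2
  ncp_for <- function(target_p) {
    # find ncp with pchisq(chisq, df, ncp) == target_p
    f <- function(l) stats::pchisq(chisq, df, ncp = l) - target_p
    if (f(0) < 0) return(NA_real_)            # even ncp=0 gives too little mass
    hi <- max(chisq * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    if (f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  # lower bound: larger tail prob; upper: smaller
  l_lo <- ncp_for(1 - a)
  l_hi <- ncp_for(a)
  lo <- if (is.na(l_lo)) 0 else sqrt(l_lo / (n * df))
  hi <- if (is.na(l_hi)) 0 else sqrt(l_hi / (n * df))
  c(lo, hi)
}

# SRMR over standardized covariance and mean residuals (means included since
# the mean structure is estimated)
srmr_value <- function(fit) {
  sat <- fit_saturated(fit$data)
  s <- sat$sigma
  m <- sat$mu
  si <- fit$implied$sigma
  mi <- fit$implied$mu
  dsd <- sqrt(diag(s))
  p <- length(m)
  res <- c()
  for (i in seq_len(p)) for (j in i:p) {
    res <- c(res, (s[i, j] - si[i, j]) / (dsd[i] * dsd[j]))
  }
  res <- c(res, (m - mi) / dsd)
  sqrt(mean(res^2))
}
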