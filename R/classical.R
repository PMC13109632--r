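#' Cronbach's alpha with half-cycle equalization
#'
#' Internal consistency from per-half-cycle values. Because data loss (e.g.
#' blinks) leaves subjects with different numbers of usable half-cycles,
#' subjects with fewer than `min_items` available half-cycles are excluded
#' first, then availability outliers at the lower end (available count below
#' `mean - iqr_mult * IQR` of the counts) are removed, and finally every
#' remaining subject is reduced to the smallest remaining availability by a
#' seeded random draw from their available half-cycles (kept in original
#' order). Alpha is then `k/(k-1) * (1 - sum of item variances / variance of
#' the sum)`.
#'
#' @param x Matrix of subjects x half-cycles (NA = unavailable).
#' @param seed Integer seed for the equalization draw (required; no silent
#'   default).
#' @param min_items Minimum number of available half-cycles (default 30).
#' @param iqr_mult Multiplier of the lower-end availability outlier fence.
#' @return List with `alpha`, `k` (items used), `n` (subjects used),
#'   `excluded` (subjects dropped). `alpha` is `NA` when fewer than 2 items
#'   or 2 subjects remain.
#' @export
cronbach_alpha_equalized <- function(x, seed, min_items = 30, iqr_mult = 4) {
  if (missing(seed)) stop("`seed` is required for the equalization draw",
                          call. = FALSE)
  x <- as.matrix(x)
  avail <- rowSums(!is.na(x))
  keep <- avail >= min_items
  counts <- avail[keep]
  if (length(counts)) {
    fence <- mean(counts) - iqr_mult * stats::IQR(counts)
    keep[keep] <- counts >= fence
  }
  if (sum(keep) < 2) {
    return(list(alpha = NA_real_, k = NA_integer_, n = sum(keep),
                excluded = which(!keep)))
  }
  xs <- x[keep, , drop = FALSE]
  k <- min(rowSums(!is.na(xs)))
  if (k < 2) {
    return(list(alpha = NA_real_, k = k, n = nrow(xs),
                excluded = which(!keep)))
  }
  rs <- get_rng_state()
  on.exit(set_rng_state(rs), add = TRUE)
  set.seed(seed)
  items <- t(apply(xs, 1, function(row) {
    av <- which(!is.na(row))
    row[sort(sample(av, k))]
  }))
  alpha <- alpha_from_items(items)
  list(alpha = alpha, k = as.integer(k), n = nrow(items),
       excluded = which(!keep))
}

alpha_from_items <- function(items) {
  k <- ncol(items)
  item_vars <- apply(items, 2, stats::var)
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0) return(NA_real_)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Split-half reliability as a Spearman correlation
#'
#' Rank correlation between scores computed from the odd and the even halves
#' (used for variables that cannot be computed per half-cycle).
#'
#' @param odd,even Paired per-subject scores from the two halves.
#' @return Spearman's rho, `NA` when fewer than 3 complete pairs remain or a
#'   half has zero variance.
#' @export
split_half_spearman <- function(odd, even) {
  ok <- stats::complete.cases(odd, even)
  odd <- odd[ok]; even <- even[ok]
  if (length(odd) < 3) return(NA_real_)
  if (stats::sd(odd) == 0 || stats::sd(even) == 0) return(NA_real_)
  stats::cor(odd, even, method = "spearman")
}

#' Two-way mixed single-measures ICC with absolute agreement
#'
#' ICC(A,1): `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#' from the two-way ANOVA decomposition of a subjects x occasions table,
#' with the F-based confidence interval of McGraw and Wong. Incomplete rows
#' are removed listwise.
#'
#' @param x Matrix/data frame of subjects x occasions.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n`, `k`, and the mean
#'   squares.
#' @export
icc_a1 <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 occasions", call. = FALSE)
  if (n < 2) stop("need at least 2 complete cases", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))

  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf_level
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms_r - f_l * ms_e) /
    (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
  upper <- n * (f_u * ms_r - ms_e) /
    (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
  list(icc = icc, lower = lower, upper = upper, n = n, k = k,
       ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e)
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Within-subject decomposition of a subjects x occasions table:
#' F test of the occasion effect with partial eta squared, Mauchly's
#' sphericity test, the Greenhouse-Geisser epsilon with the corrected
#' p-value, and (when the governing p-value is significant) Bonferroni-
#' corrected post hoc paired t tests with Cohen's d based on the SD of the
#' difference scores. Incomplete rows are removed listwise.
#'
#' @param x Matrix/data frame of subjects x occasions (at least 2; with 2
#'   occasions sphericity holds trivially and the F test equals the squared
#'   paired t test).
#' @param alpha Significance level gating the post hoc tests.
#' @return List of class `rm_anova`: `f`, `df_n`, `df_d`, `p`, `eta_p2`,
#'   `mauchly_w`, `mauchly_p`, `gg_epsilon`, `p_gg`, `p_governing`,
#'   `post_hoc` (data frame or `NULL`), `n`.
#' @export
rm_anova <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 occasions", call. = FALSE)
  if (n < 3) stop("need at least 3 complete cases", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_occ <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_occ
  df_n <- k - 1
  df_d <- (n - 1) * (k - 1)
  ms_occ <- ss_occ / df_n
  ms_err <- ss_err / df_d
  f <- ms_occ / ms_err
  p <- stats::pf(f, df_n, df_d, lower.tail = FALSE)
  eta_p2 <- ss_occ / (ss_occ + ss_err)

  # Mauchly's W on the orthonormal-contrast covariance (trivial for k = 2)
  if (k > 2) {
    s <- stats::cov(x)
    cm <- contr_orthonormal(k)
    a <- cm %*% s %*% t(cm)
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    w <- prod(ev) / (mean(ev))^(k - 1)
    d_m <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    chi <- -(n - 1) * d_m * log(w)
    df_m <- k * (k - 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi, df_m, lower.tail = FALSE)
    gg <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  } else {
    w <- 1
    mauchly_p <- 1
    gg <- 1
  }
  p_gg <- stats::pf(f, gg * df_n, gg * df_d, lower.tail = FALSE)
  p_gov <- if (mauchly_p < alpha) p_gg else p

  post <- NULL
  if (p_gov < alpha) {
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    post <- data.frame(pair = character(m), t = numeric(m), df = numeric(m),
                       p_raw = numeric(m), p_bonf = numeric(m),
                       d = numeric(m))
    for (j in seq_len(m)) {
      a_i <- pairs[1, j]; b_i <- pairs[2, j]
      diff <- x[, a_i] - x[, b_i]
      tt <- stats::t.test(diff)
      post$pair[j] <- sprintf("T%d vs T%d", a_i, b_i)
      post$t[j] <- unname(tt$statistic)
      post$df[j] <- unname(tt$parameter)
      post$p_raw[j] <- tt$p.value
      post$p_bonf[j] <- min(1, tt$p.value * m)
      post$d[j] <- mean(diff) / stats::sd(diff)
    }
  }
  structure(list(f = f, df_n = df_n, df_d = df_d, p = p, eta_p2 = eta_p2,
                 mauchly_w = w, mauchly_p = mauchly_p, gg_epsilon = gg,
                 p_gg = p_gg, p_governing = p_gov, post_hoc = post, n = n),
            class = "rm_anova")
}

# (k-1) x k orthonormal contrast matrix (Helmert, normalized)
contr_orthonormal <- function(k) {
  h <- stats::contr.helmert(k)
  t(apply(h, 2, function(v) v / sqrt(sum(v^2))))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.4f (n = %d)\n",
              x$df_n, x$df_d, x$f, x$p, x$eta_p2, x$n))
  cat(sprintf("  Mauchly W = %.4f (p = %.4g); GG epsilon = %.3f, corrected p = %.4g\n",
              x$mauchly_w, x$mauchly_p, x$gg_epsilon, x$p_gg))
  if (!is.null(x$post_hoc)) {
    cat("  Bonferroni post hoc paired t tests:\n")
    print(x$post_hoc, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
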