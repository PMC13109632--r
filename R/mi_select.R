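#' Longitudinal measurement-invariance ladder
#'
#' Fits the latent state (LS) model at increasing invariance levels -
#' configural, weak (equal state loadings), strong (+ manifest intercepts
#' zero, free state means), strict (+ equal error variances;
#' tau-equivalence) - and compares each rung to the previous by chi-square
#' difference test. A restriction is retained when the test is not
#' significant at `alpha` *or* the CFI change stays below `delta_cfi`
#' (fit-index override). An indicator-specific method factor is also tested
#' against the configural model to check indicator homogeneity.
#'
#' @param data Manifest data (matrix / data frame / [sem_data]).
#' @param n_indicators Indicators per occasion.
#' @param n_occasions Occasions.
#' @param robust Use scaled difference tests (fits get
#'   [robust_correction()]).
#' @param alpha Significance level of the difference tests.
#' @param delta_cfi CFI-change threshold below which a restriction is
#'   retained regardless of the test.
#' @param indicator_specific Indicator index for the homogeneity check.
#' @param restarts Starts per fit, see [fit_ml()].
#' @return List of class `mi_ladder`: `fits` (per rung), `comparisons`,
#'   `verdict` (highest supported level or `"inconclusive"`),
#'   `indicator_specific_needed`, and `recommendation` (non-`NULL` when
#'   strong invariance fails).
#' @export
mi_ladder <- function(data, n_indicators = 2, n_occasions = 3,
                      robust = FALSE, alpha = 0.05, delta_cfi = 0.01,
                      indicator_specific = 2L, restarts = 3) {
  sd <- sem_data(prep_manifest(data, n_occasions, n_indicators))
  levels <- c("configural", "weak", "strong", "strict")
  fits <- list()
  for (lv in levels) {
    spec <- lst_model_spec("LS", n_indicators, n_occasions, mi_level = lv)
    f <- fit_ml(spec, sd, restarts = restarts)
    if (robust) f <- robust_correction(f)
    fits[[lv]] <- f
  }
  bad <- names(fits)[!vapply(fits, function(f) f$converged, logical(1))]
  comparisons <- list()
  verdict <- "configural"
  if (length(bad)) {
    verdict <- "inconclusive"
  } else {
    for (j in 2:4) {
      cmp <- chi2_difference(fits[[j]], fits[[j - 1]], scaled = robust)
      cmp$step <- paste(levels[j - 1], "->", levels[j])
      comparisons[[length(comparisons) + 1L]] <- cmp
      rejected <- cmp$p_value < alpha && abs(cmp$delta_cfi) >= delta_cfi
      if (rejected) break
      verdict <- levels[j]
    }
  }

  is_fit <- NULL
  is_needed <- NA
  if (indicator_specific > 0 && verdict != "inconclusive") {
    spec_is <- lst_model_spec("LS", n_indicators, n_occasions,
                              mi_level = "configural",
                              indicator_specific = indicator_specific)
    is_fit <- fit_ml(spec_is, sd, restarts = restarts)
    if (robust && is_fit$converged) is_fit <- robust_correction(is_fit)
    if (is_fit$converged) {
      cmp_is <- chi2_difference(fits[["configural"]], is_fit, scaled = robust)
      cmp_is$step <- "configural -> + indicator-specific factor"
      comparisons[[length(comparisons) + 1L]] <- cmp_is
      is_needed <- cmp_is$p_value < alpha && abs(cmp_is$delta_cfi) >= delta_cfi
    }
  }

  rec <- NULL
  if (verdict %in% c("configural", "weak")) {
    rec <- sprintf(paste0("strong measurement invariance not supported with %d ",
                          "indicators; refit using %d indicators per occasion"),
                   n_indicators, n_indicators + 1L)
  }
  if (verdict == "inconclusive") {
    rec <- sprintf("non-convergent rung(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(fits = fits, comparisons = comparisons, verdict = verdict,
                 indicator_specific_fit = is_fit,
                 indicator_specific_needed = is_needed,
                 recommendation = rec),
            class = "mi_ladder")
}

#' @export
print.mi_ladder <- function(x, ...) {
  cat("Measurement-invariance ladder\n")
  for (cmp in x$comparisons) {
    cat(sprintf("  %-45s dchisq %.3f (ddf %d), p = %.4g, dCFI = %+.4f\n",
                cmp$step, cmp$dchisq, cmp$ddf, cmp$p_value, cmp$delta_cfi))
  }
  cat("  verdict:", x$verdict, "\n")
  if (isTRUE(x$indicator_specific_needed)) {
    cat("  indicator-specific factor indicated\n")
  }
  if (!is.null(x$recommendation)) cat("  note:", x$recommendation, "\n")
  invisible(x)
}

prep_manifest <- function(data, n_occasions, n_indicators) {
  if (inherits(data, "sem_data")) return(data)
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "subject"), drop = FALSE]
  data <- as.matrix(data)
  want <- manifest_names(n_occasions, n_indicators)
  if (!is.null(colnames(data)) && all(want %in% colnames(data))) {
    data <- data[, want, drop = FALSE]
  }
  data
}

#' Reduce one model family along the restriction ladder
#'
#' Starting from the unrestricted model of a family, applies the
#' restrictions A (equal error variances), B (+ equal state-residual
#' variances, trait loadings 1) and C (+ state loadings 1) one at a time,
#' keeping each restriction unless the chi-square difference test rejects it
#' (subject to the CFI-change override). Negative-variance remedies are
#' applied automatically: a negative error variance triggers a refit with
#' that variance fixed to 0; a negative slope variance (LGC) triggers a
#' refit with the third slope loading fixed to its estimate from the
#' less-restrictive model. If free estimation of the third slope loading
#' fails, fixed values are tried in the order: previous estimate, 2, 1.5, 1.
#'
#' @param data Manifest data.
#' @param family `"LST"`, `"LST_T"`, `"LGC"` or `"LT"`.
#' @inheritParams mi_ladder
#' @return List with `fit` (most restrictive retained fit), `restriction`,
#'   `trace` (text log of every decision), `comparisons`.
#' @export
reduce_family <- function(data, family, n_indicators = 2, n_occasions = 3,
                          robust = FALSE, alpha = 0.05, delta_cfi = 0.01,
                          restarts = 3) {
  sd <- sem_data(prep_manifest(data, n_occasions, n_indicators))
  trace <- character(0)
  comparisons <- list()

  fit_step <- function(restriction, sigma3_prev = NULL) {
    fit_with_remedies(sd, family, n_indicators, n_occasions, restriction,
                      robust, restarts, sigma3_prev)
  }
  res <- fit_step("none")
  current <- res$fit
  trace <- c(trace, res$trace)
  if (is.null(current) || !current$converged) {
    return(list(fit = current, restriction = "none",
                trace = c(trace, "unrestricted model did not converge"),
                comparisons = comparisons))
  }
  kept <- "none"
  for (r in c("A", "B", "C")) {
    s3_prev <- if (family == "LGC") current$params$sigma[3] else NULL
    res <- fit_step(r, sigma3_prev = s3_prev)
    trace <- c(trace, res$trace)
    cand <- res$fit
    if (is.null(cand) || !cand$converged) {
      trace <- c(trace, sprintf("restriction %s: no converged fit; ladder stops", r))
      break
    }
    cmp <- tryCatch(chi2_difference(cand, current, scaled = robust),
                    error = function(e) NULL)
    if (is.null(cmp)) {
      trace <- c(trace, sprintf("restriction %s: not nested in current model; ladder stops", r))
      break
    }
    cmp$step <- sprintf("%s: %s -> %s", family, kept, r)
    comparisons[[length(comparisons) + 1L]] <- cmp
    rejected <- cmp$p_value < alpha && abs(cmp$delta_cfi) >= delta_cfi
    trace <- c(trace, sprintf(
      "%s restriction %s vs %s: dchisq %.3f (ddf %d), p = %.4g, dCFI = %+.4f -> %s",
      family, r, kept, cmp$dchisq, cmp$ddf, cmp$p_value, cmp$delta_cfi,
      if (rejected) "rejected" else "retained"))
    if (rejected) break
    current <- cand
    kept <- r
  }
  list(fit = current, restriction = kept, trace = trace,
       comparisons = comparisons)
}

# fit one (family, restriction) with the negative-variance remedies
fit_with_remedies <- function(sd, family, n_indicators, n_occasions,
                              restriction, robust, restarts, sigma3_prev) {
  trace <- character(0)
  mk <- function(sigma3 = "free", fixed_zero = integer(0)) {
    lst_model_spec(family, n_indicators, n_occasions,
                   restriction = restriction,
                   sigma3 = if (family == "LGC") sigma3 else "free",
                   fixed_zero_eps = fixed_zero)
  }
  do_fit <- function(spec) {
    f <- fit_ml(spec, sd, restarts = restarts)
    if (robust && f$converged) f <- robust_correction(f)
    f
  }
  fit <- do_fit(mk())
  # sigma3 fallback ladder when free estimation fails (LGC only)
  if (family == "LGC" && !fit$converged) {
    cands <- c(sigma3_prev, 2, 1.5, 1)
    for (s3 in cands) {
      trace <- c(trace, sprintf(
        "LGC %s: free sigma3 did not converge; trying sigma3 = %.4g",
        restriction, s3))
      fit <- do_fit(mk(sigma3 = s3))
      if (fit$converged) break
    }
  }
  # negative error variance -> fix that eps to 0 and refit
  guard <- 0
  while (fit$converged && any(grepl("^eps", fit$neg_variances)) && guard < 4) {
    guard <- guard + 1
    est <- fit$theta
    ptab <- fit$spec$ptab
    eps_rows <- ptab[ptab$mat == "eps" & ptab$free, ]
    neg_lab <- intersect(fit$neg_variances, eps_rows$label)
    if (!length(neg_lab)) break
    bad <- eps_rows[eps_rows$label == neg_lab[1], ][1, ]
    idx <- (bad$i - 1) * n_indicators + bad$k
    trace <- c(trace, sprintf(
      "%s %s: error variance %s negative (%.4g); refit with it fixed to 0",
      family, restriction, neg_lab[1], est[neg_lab[1]]))
    fz <- union(fit$spec$fixed_zero_eps, idx)
    fit <- do_fit(mk(sigma3 = fit$spec$sigma3, fixed_zero = fz))
  }
  # negative slope variance -> fix sigma3 to the less-restrictive estimate
  if (family == "LGC" && fit$converged && "var_sl" %in% fit$neg_variances &&
      !is.null(sigma3_prev) && identical(fit$spec$sigma3, "free")) {
    trace <- c(trace, sprintf(
      "LGC %s: slope variance negative; refit with sigma3 fixed to %.4g from the less restrictive model",
      restriction, sigma3_prev))
    fit <- do_fit(mk(sigma3 = sigma3_prev, fixed_zero = fit$spec$fixed_zero_eps))
  }
  list(fit = fit, trace = trace)
}

#' Select the most restrictive best-fitting model across families
#'
#' Reduces each candidate family (LST, LST_T, LGC) along its restriction
#' ladder, eliminates preselected models that fit significantly worse than
#' others by (scaled) chi-square difference tests, screens survivors against
#' the fit-index thresholds (CFI >= 0.95, RMSEA <= 0.06, SRMR <= 0.08), and
#' among adequate models picks the most restrictive (largest df). An LGC
#' survivor is preferred over LST_T only when its slope mean or slope
#' standard deviation is significant (critical ratio >= 1.96); otherwise the
#' model without trait change wins.
#'
#' @param data Manifest data.
#' @param families Families to consider.
#' @inheritParams mi_ladder
#' @param cfi_min,rmsea_max,srmr_max Adequacy thresholds.
#' @return List of class `model_selection`: `family`, `fit`, `reductions`,
#'   `indices`, `adequate`, `trace`.
#' @export
select_model <- function(data, families = c("LST", "LST_T", "LGC"),
                         n_indicators = 2, n_occasions = 3, robust = FALSE,
                         alpha = 0.05, delta_cfi = 0.01, restarts = 3,
                         cfi_min = 0.95, rmsea_max = 0.06, srmr_max = 0.08) {
  sd <- sem_data(prep_manifest(data, n_occasions, n_indicators))
  trace <- character(0)
  red <- list()
  for (fam in families) {
    red[[fam]] <- reduce_family(sd, fam, n_indicators, n_occasions,
                                robust = robust, alpha = alpha,
                                delta_cfi = delta_cfi, restarts = restarts)
    trace <- c(trace, red[[fam]]$trace)
  }
  ok <- vapply(red, function(r) !is.null(r$fit) && r$fit$converged, logical(1))
  cand <- names(red)[ok]
  if (!length(cand)) {
    return(structure(list(family = NA_character_, fit = NULL, reductions = red,
                          indices = NULL, adequate = FALSE,
                          trace = c(trace, "no family converged")),
                     class = "model_selection"))
  }

  # pairwise elimination: where two preselected models differ in df, test the
  # more restrictive against the fuller; eliminate it when rejected
  alive <- cand
  for (a in cand) for (b in cand) {
    if (a == b || !(a %in% alive)) next
    fa <- red[[a]]$fit; fb <- red[[b]]$fit
    if (fa$df <= fb$df) next
    cmp <- tryCatch(chi2_difference(fa, fb, scaled = robust),
                    error = function(e) NULL)
    if (is.null(cmp)) next
    worse <- cmp$p_value < alpha && abs(cmp$delta_cfi) >= delta_cfi
    trace <- c(trace, sprintf(
      "compare %s (df %d) vs %s (df %d): dchisq %.3f, p = %.4g, dCFI = %+.4f -> %s",
      a, fa$df, b, fb$df, cmp$dchisq, cmp$p_value, cmp$delta_cfi,
      if (worse) paste(a, "eliminated") else "no elimination"))
    if (worse) alive <- setdiff(alive, a)
  }

  idx <- lapply(red[alive], function(r) {
    fit_indices(r$fit, scaled = robust && !is.null(r$fit$chisq_scaled) &&
                  !is.na(r$fit$scaling %||% NA))
  })
  adequate <- vapply(alive, function(fam) {
    ix <- idx[[fam]]
    isTRUE(ix$cfi >= cfi_min) && isTRUE(ix$rmsea <= rmsea_max) &&
      isTRUE(ix$srmr <= srmr_max)
  }, logical(1))
  pool <- alive[adequate]
  no_adequate <- FALSE
  if (!length(pool)) {
    no_adequate <- TRUE
    pool <- alive
    trace <- c(trace, "no candidate meets all fit-index thresholds; reporting best-fitting model with a no-adequate-model flag")
  } else {
    trace <- c(trace, sprintf("adequate by fit indices: %s",
                              paste(pool, collapse = ", ")))
  }

  # LGC needs evidence of trait change to beat LST_T
  if (all(c("LGC", "LST_T") %in% pool)) {
    cr <- critical_ratios(red[["LGC"]]$fit)
    get_cr <- function(lab) {
      v <- cr$cr[cr$label == lab]
      if (length(v)) abs(v) else NA_real_
    }
    slope_sig <- isTRUE(get_cr("mu_sl") >= 1.96) ||
      isTRUE(sqrt_cr_var_sl(red[["LGC"]]$fit) >= 1.96)
    if (!slope_sig) {
      pool <- setdiff(pool, "LGC")
      trace <- c(trace, "LGC slope mean and slope SD both nonsignificant (c.r. < 1.96): LST_T preferred over LGC")
    } else {
      trace <- c(trace, "LGC indicates trait change (significant slope mean or SD)")
    }
  }
  dfs <- vapply(pool, function(fam) red[[fam]]$fit$df, numeric(1))
  sel <- pool[which.max(dfs)]
  trace <- c(trace, sprintf("selected: %s (%s), df = %d%s", sel,
                            red[[sel]]$restriction, red[[sel]]$fit$df,
                            if (no_adequate) " [no adequate model]" else ""))
  structure(list(family = sel, fit = red[[sel]]$fit, reductions = red,
                 indices = idx, adequate = !no_adequate, trace = trace),
            class = "model_selection")
}

# c.r. of the slope SD: delta-method from the slope variance estimate
sqrt_cr_var_sl <- function(fit) {
  j <- match("var_sl", fit$par_table$label)
  if (is.na(j)) return(NA_real_)
  est <- fit$par_table$estimate[j]
  se <- if (!is.null(fit$se_robust) && !is.na(fit$se_robust[j]))
    fit$se_robust[j] else fit$par_table$se[j]
  if (is.na(se) || se <= 0 || est <= 0) return(NA_real_)
  # SD = sqrt(var): se(SD) = se(var) / (2 sqrt(var))
  sqrt(est) / (se / (2 * sqrt(est)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection trace\n")
  for (line in x$trace) cat(" -", line, "\n")
  invisible(x)
}
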