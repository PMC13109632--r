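#' Reliability, consistency and occasion specificity of a fitted model
#'
#' For every manifest variable X_ik of a fitted LST, LST_T or LGC model,
#' decomposes its model-implied variance into
#' * consistency `Con(X_ik)` - the trait share: `lambda_ik^2 gamma_i^2
#'   Var(T) / Var(X_ik)` for LST-type models, plus slope variance and
#'   trait-slope covariance terms for LGC models;
#' * occasion specificity `Spe(X_ik) = lambda_ik^2 Var(SR_i) / Var(X_ik)` -
#'   the share due to the situation and person-situation interaction;
#' * reliability `Rel = Con + Spe` (the identity holds exactly because
#'   `Var(X_ik)` is model-implied).
#'
#' @param fit A converged [lst_fit] with family LST, LST_T or LGC.
#' @return Data frame of class `variance_decomposition` with columns
#'   `occasion`, `indicator`, `rel`, `con`, `spe`; the family is kept as an
#'   attribute.
#' @export
decompose_fit <- function(fit) {
  stopifnot(inherits(fit, "lst_fit"))
  fam <- fit$spec$family
  if (!fam %in% c("LST", "LST_T", "LGC")) {
    stop(sprintf("variance decomposition is defined for LST/LST_T/LGC models, not %s",
                 fam), call. = FALSE)
  }
  st <- fit$params
  k_n <- fit$spec$n_indicators
  vx_all <- diag(fit$implied$sigma)
  out <- expand.grid(indicator = seq_len(k_n),
                     occasion = seq_len(fit$spec$n_occasions))
  out <- out[, c("occasion", "indicator")]
  con <- spe <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    i <- out$occasion[r]; k <- out$indicator[r]
    vx <- vx_all[(i - 1) * k_n + k]
    if (vx <= 0) {
      con[r] <- spe[r] <- NA_real_
      next
    }
    la2 <- st$lambda[i, k]^2
    trait_var <- st$gamma[i]^2 * st$var_t
    if (fam == "LGC") {
      trait_var <- trait_var + st$sigma[i]^2 * st$var_sl +
        2 * st$gamma[i] * st$sigma[i] * st$cov_tsl
    }
    con[r] <- la2 * trait_var / vx
    spe[r] <- la2 * st$var_sr[i] / vx
  }
  out$rel <- con + spe
  out$con <- con
  out$spe <- spe
  out <- out[, c("occasion", "indicator", "rel", "con", "spe")]
  attr(out, "family") <- fam
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Average a decomposition over occasions and indicators
#'
#' @param decomp A [decompose_fit()] result.
#' @return One-row data frame with the mean `rel`, `con`, `spe` over all
#'   indicator-occasion cells (equal cell weights).
#' @export
average_decomposition <- function(decomp) {
  data.frame(rel = mean(decomp$rel), con = mean(decomp$con),
             spe = mean(decomp$spe))
}

#' Summarize averaged decompositions across variables
#'
#' Takes one averaged `rel`/`con`/`spe` row per dependent variable and
#' computes the reporting summaries: per-variable trait share
#' (`100 * con / rel`), grand means across variables, the grand-mean trait
#' share, and the extrema of each column. Values are summarized unrounded;
#' rounded reporting columns (2 decimals, integer percent) are attached.
#'
#' @param x Data frame with columns `variable`, `rel`, `con`, `spe` (one row
#'   per variable).
#' @return List of class `decomposition_summary` with `per_variable`,
#'   `grand` (means plus `trait_share_pct`), and `extrema`.
#' @export
summarize_decomposition <- function(x) {
  stopifnot(all(c("variable", "rel", "con", "spe") %in% names(x)),
            nrow(x) >= 1)
  pv <- x[, c("variable", "rel", "con", "spe")]
  pv$trait_share_pct <- 100 * pv$con / pv$rel
  pv$rel_2 <- round(pv$rel, 2)
  pv$con_2 <- round(pv$con, 2)
  pv$spe_2 <- round(pv$spe, 2)
  pv$trait_share_pct_0 <- round(pv$trait_share_pct)
  grand <- list(rel = mean(pv$rel), con = mean(pv$con), spe = mean(pv$spe),
                trait_share_pct = mean(pv$trait_share_pct))
  extrema <- list(con_range = range(pv$con), spe_range = range(pv$spe),
                  rel_range = range(pv$rel))
  structure(list(per_variable = pv, grand = grand, extrema = extrema),
            class = "decomposition_summary")
}

#' @export
print.decomposition_summary <- function(x, ...) {
  cat("Variance decomposition summary\n")
  print(x$per_variable[, c("variable", "rel_2", "con_2", "spe_2",
                           "trait_share_pct_0")], row.names = FALSE)
  cat(sprintf("grand means: Rel %.2f, Con %.2f, Spe %.2f; trait share %d%%\n",
              x$grand$rel, x$grand$con, x$grand$spe,
              round(x$grand$trait_share_pct)))
  invisible(x)
}

#' Reference averaged decomposition values
#'
#' Averaged reliability, consistency and occasion-specificity values for the
#' ten dependent variables (five per task) of a published three-occasion
#' smooth-pursuit reliability study, as shipped in `inst/extdata`. Used by
#' the worked examples to exercise [summarize_decomposition()].
#'
#' @return Data frame with columns `task`, `variable`, `rel`, `con`, `spe`.
#' @export
reference_decomposition <- function() {
  path <- system.file("extdata", "spem_decomposition_averages.csv",
                      package = "pursuitlst", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
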