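#' Specify a latent state / state-trait / growth-curve model
#'
#' Builds the parameter table and implied-moment structure of one model from
#' the LS / LST / LGC family for `n_occasions` occasions with `n_indicators`
#' indicators (test sets) per occasion.
#'
#' Families:
#' * `"LS"` - latent state model: one state factor per occasion, freely
#'   correlated; used for measurement-invariance testing (`mi_level`).
#' * `"LST"` - states decomposed into a trait plus occasion-specific state
#'   residuals; state intercepts freely estimated (trait mean fixed 0).
#' * `"LST_T"` - as LST but state intercepts fixed to 0 and the trait mean
#'   estimated, i.e. no occasion-level mean shifts.
#' * `"LGC"` - second-order latent growth curve: adds a slope factor with
#'   loadings `0, 1, sigma3` capturing trait change; trait and slope means
#'   free.
#' * `"LT"` - trait-only model: no state residuals (all their variances fixed
#'   to 0), manifest variables decompose into trait and error.
#'
#' Restriction ladder (`restriction`) for LST/LST_T/LGC/LT: `"A"` equal
#' measurement error variances; `"B"` additionally equal state-residual
#' variances and trait loadings fixed to 1; `"C"` additionally state loadings
#' fixed to 1. Measurement-invariance levels (`mi_level`) for LS:
#' `"configural"` (free loadings/intercepts per occasion), `"weak"` (equal
#' loadings), `"strong"` (+ intercepts zero, free state means), `"strict"`
#' (+ equal error variances).
#'
#' @param family Model family (see Details).
#' @param n_indicators Indicators per occasion (2-4).
#' @param n_occasions Number of occasions (3 for LGC).
#' @param restriction Restriction-ladder position for LST/LST_T/LGC/LT.
#' @param mi_level Invariance level for LS models.
#' @param indicator_specific 0 for none, otherwise the indicator index that
#'   receives an indicator-specific method factor (loadings fixed to 1).
#' @param sigma3 `"free"` or a fixed numeric value for the third slope
#'   loading (LGC only).
#' @param fixed_zero_eps Integer vector of manifest-variable indices
#'   (occasion-major) whose error variance is fixed to 0 (negative-variance
#'   remedy).
#' @return Object of class `lst_model_spec`.
#' @export
lst_model_spec <- function(family = c("LST", "LST_T", "LGC", "LS", "LT"),
                           n_indicators = 2,
                           n_occasions = 3,
                           restriction = c("none", "A", "B", "C"),
                           mi_level = c("configural", "weak", "strong", "strict"),
                           indicator_specific = 0L,
                           sigma3 = "free",
                           fixed_zero_eps = integer(0)) {
  family <- match.arg(family)
  restriction <- match.arg(restriction)
  mi_level <- match.arg(mi_level)
  if (!n_indicators %in% 2:4) stop("`n_indicators` must be 2-4", call. = FALSE)
  if (family == "LGC" && n_occasions != 3) {
    stop("LGC models are defined for 3 occasions", call. = FALSE)
  }
  i_n <- as.integer(n_occasions)
  k_n <- as.integer(n_indicators)
  p <- i_n * k_n

  rows <- list()
  add <- function(mat, i, k, label, free, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, i = i, k = k, label = label, free = free, value = value,
      stringsAsFactors = FALSE)
  }

  if (family == "LS") {
    for (i in seq_len(i_n)) for (k in seq_len(k_n)) {
      if (k == 1) {
        add("lambda", i, k, sprintf("la%d_%d", i, k), FALSE, 1)
      } else if (mi_level == "configural") {
        add("lambda", i, k, sprintf("la%d_%d", i, k), TRUE, 1)
      } else {
        add("lambda", i, k, sprintf("la%d", k), TRUE, 1)
      }
      if (k == 1 || mi_level %in% c("strong", "strict")) {
        add("nu", i, k, sprintf("nu%d_%d", i, k), FALSE, 0)
      } else {
        add("nu", i, k, sprintf("nu%d_%d", i, k), TRUE, 0)
      }
      if (mi_level == "strict") {
        add("eps", i, k, "eps", TRUE, 0.1)
      } else {
        add("eps", i, k, sprintf("eps%d_%d", i, k), TRUE, 0.1)
      }
    }
    for (i in seq_len(i_n)) {
      add("s_mean", i, 0L, sprintf("sm%d", i), TRUE, 0)
      for (j in i:i_n) {
        add("phi", i, j, sprintf("phi%d_%d", i, j), TRUE,
            if (i == j) 1 else 0.5)
      }
    }
  } else {
    for (i in seq_len(i_n)) for (k in seq_len(k_n)) {
      if (k == 1 || restriction == "C") {
        add("lambda", i, k, sprintf("la%d_%d", i, k), FALSE, 1)
      } else {
        add("lambda", i, k, sprintf("la%d", k), TRUE, 1)
      }
      idx <- (i - 1L) * k_n + k
      if (idx %in% fixed_zero_eps) {
        add("eps", i, k, sprintf("eps0_%d", idx), FALSE, 0)
      } else if (restriction %in% c("A", "B", "C")) {
        add("eps", i, k, "eps", TRUE, 0.1)
      } else {
        add("eps", i, k, sprintf("eps%d_%d", i, k), TRUE, 0.1)
      }
      add("nu", i, k, sprintf("nu%d_%d", i, k), FALSE, 0)
    }
    for (i in seq_len(i_n)) {
      if (i == 1 || restriction %in% c("B", "C")) {
        add("gamma", i, 0L, sprintf("ga%d", i), FALSE, 1)
      } else {
        add("gamma", i, 0L, sprintf("ga%d", i), TRUE, 1)
      }
      if (family == "LT") {
        add("var_sr", i, 0L, sprintf("vsr%d", i), FALSE, 0)
      } else if (restriction %in% c("B", "C")) {
        add("var_sr", i, 0L, "var_sr", TRUE, 0.4)
      } else {
        add("var_sr", i, 0L, sprintf("vsr%d", i), TRUE, 0.4)
      }
      if (family == "LST") {
        add("s_int", i, 0L, sprintf("si%d", i), TRUE, 0)
      } else {
        add("s_int", i, 0L, sprintf("si%d", i), FALSE, 0)
      }
    }
    add("var_t", 0L, 0L, "var_t", TRUE, 1)
    add("mu_t", 0L, 0L, "mu_t", family != "LST", 0)
    if (family == "LGC") {
      add("mu_sl", 0L, 0L, "mu_sl", TRUE, 0)
      add("var_sl", 0L, 0L, "var_sl", TRUE, 0.1)
      add("cov_tsl", 0L, 0L, "cov_tsl", TRUE, 0)
      add("sigma", 1L, 0L, "sig1", FALSE, 0)
      add("sigma", 2L, 0L, "sig2", FALSE, 1)
      if (identical(sigma3, "free")) {
        add("sigma", 3L, 0L, "sig3", TRUE, 2)
      } else {
        add("sigma", 3L, 0L, "sig3", FALSE, as.numeric(sigma3))
      }
    } else {
      for (i in seq_len(i_n)) add("sigma", i, 0L, sprintf("sig%d", i), FALSE, 0)
      add("mu_sl", 0L, 0L, "mu_sl", FALSE, 0)
      add("var_sl", 0L, 0L, "var_sl", FALSE, 0)
      add("cov_tsl", 0L, 0L, "cov_tsl", FALSE, 0)
    }
  }
  if (indicator_specific > 0) {
    if (indicator_specific > k_n) stop("invalid `indicator_specific`", call. = FALSE)
    add("var_is", 0L, 0L, "var_is", TRUE, 0.05)
  }

  ptab <- do.call(rbind, rows)
  free_labels <- unique(ptab$label[ptab$free])
  spec <- structure(
    list(family = family, n_occasions = i_n, n_indicators = k_n, p = p,
         restriction = restriction, mi_level = mi_level,
         indicator_specific = as.integer(indicator_specific),
         sigma3 = sigma3, fixed_zero_eps = fixed_zero_eps,
         ptab = ptab, free_labels = free_labels,
         npar = length(free_labels)),
    class = "lst_model_spec")
  spec
}

#' @export
print.lst_model_spec <- function(x, ...) {
  lvl <- if (x$family == "LS") paste0("MI level ", x$mi_level) else
    paste0("restriction ", x$restriction)
  cat(sprintf("<lst_model_spec> %s, %d occasions x %d indicators, %s, %d free parameters\n",
              x$family, x$n_occasions, x$n_indicators, lvl, x$npar))
  invisible(x)
}

# fill the structured parameter list from the free-parameter vector
assemble_params <- function(spec, theta) {
  ptab <- spec$ptab
  full <- ptab$value
  if (length(theta)) {
    full[ptab$free] <- theta[match(ptab$label[ptab$free], spec$free_labels)]
  }
  i_n <- spec$n_occasions
  k_n <- spec$n_indicators
  st <- list(lambda = matrix(1, i_n, k_n), eps = matrix(0, i_n, k_n),
             nu = matrix(0, i_n, k_n), gamma = rep(1, i_n),
             var_sr = rep(0, i_n), s_int = rep(0, i_n),
             sigma = rep(0, i_n), s_mean = rep(0, i_n),
             phi = matrix(0, i_n, i_n),
             var_t = 0, mu_t = 0, mu_sl = 0, var_sl = 0, cov_tsl = 0,
             var_is = 0)
  for (r in seq_len(nrow(ptab))) {
    m <- ptab$mat[r]; i <- ptab$i[r]; k <- ptab$k[r]; v <- full[r]
    switch(m,
           lambda = { st$lambda[i, k] <- v },
           eps = { st$eps[i, k] <- v },
           nu = { st$nu[i, k] <- v },
           gamma = { st$gamma[i] <- v },
           var_sr = { st$var_sr[i] <- v },
           s_int = { st$s_int[i] <- v },
           sigma = { st$sigma[i] <- v },
           s_mean = { st$s_mean[i] <- v },
           phi = { st$phi[i, k] <- v; st$phi[k, i] <- v },
           var_t = { st$var_t <- v },
           mu_t = { st$mu_t <- v },
           mu_sl = { st$mu_sl <- v },
           var_sl = { st$var_sl <- v },
           cov_tsl = { st$cov_tsl <- v },
           var_is = { st$var_is <- v })
  }
  st
}

#' Model-implied mean vector and covariance matrix
#'
#' Evaluates the implied moments of a specified model at a free-parameter
#' vector. Manifest variables are ordered occasion-major
#' (`x1_1, x1_2, ..., x3_K`).
#'
#' @param spec An [lst_model_spec].
#' @param theta Free-parameter vector in the order of `spec$free_labels`.
#' @return List with `mu` (length p) and `sigma` (p x p).
#' @export
implied_moments <- function(spec, theta) {
  st <- assemble_params(spec, theta)
  implied_from_params(spec, st)
}

implied_from_params <- function(spec, st) {
  i_n <- spec$n_occasions
  k_n <- spec$n_indicators
  p <- spec$p
  if (spec$family == "LS") {
    phi_s <- st$phi
    m_s <- st$s_mean
  } else {
    phi_s <- outer(st$gamma, st$gamma) * st$var_t +
      outer(st$sigma, st$sigma) * st$var_sl +
      (outer(st$gamma, st$sigma) + outer(st$sigma, st$gamma)) * st$cov_tsl +
      diag(st$var_sr, i_n)
    m_s <- st$s_int + st$gamma * st$mu_t + st$sigma * st$mu_sl
  }
  b <- matrix(0, p, i_n)
  for (i in seq_len(i_n)) {
    b[(i - 1L) * k_n + seq_len(k_n), i] <- st$lambda[i, ]
  }
  sigma <- b %*% phi_s %*% t(b) + diag(as.vector(t(st$eps)), p)
  if (spec$indicator_specific > 0) {
    u <- rep(0, p)
    u[(seq_len(i_n) - 1L) * k_n + spec$indicator_specific] <- 1
    sigma <- sigma + st$var_is * tcrossprod(u)
  }
  mu <- as.vector(t(st$nu)) + drop(b %*% m_s)
  list(mu = mu, sigma = sigma)
}

# canonical manifest-variable names, occasion-major
manifest_names <- function(n_occasions, n_indicators) {
  as.vector(t(outer(seq_len(n_occasions), seq_len(n_indicators),
                    function(i, k) sprintf("x%d_%d", i, k))))
}
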