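test_that("alpha is 1 for perfectly consistent items and ~0 for pure noise", {
  set.seed(111)
  subj <- rnorm(40, 0, 2)
  x <- matrix(rep(subj, 30), 40, 30)          # identical items per subject
  a <- cronbach_alpha_equalized(x, seed = 1)
  expect_equal(a$alpha, 1, tolerance = 1e-12)

  noise <- matrix(rnorm(500 * 30), 500, 30)
  a0 <- cronbach_alpha_equalized(noise, seed = 2)
  expect_lt(abs(a0$alpha), 0.1)
})

test_that("alpha equals the direct variance-sum formula on a 2-item table", {
  set.seed(113)
  t2 <- matrix(rnorm(120), 60, 2) + rnorm(60)
  a <- cronbach_alpha_equalized(t2, seed = 3, min_items = 2)
  oracle <- 2 * (1 - (var(t2[, 1]) + var(t2[, 2])) / var(rowSums(t2)))
  expect_equal(a$alpha, oracle, tolerance = 1e-12)
})

test_that("availability exclusions and the equalization draw behave as specified", {
  set.seed(115)
  x <- matrix(rnorm(17 * 60), 17, 60) + rnorm(17) * 2
  # availabilities: 56-60 for most, 50 for one subject, 20 for another
  avail <- c(rep(56:60, 3), 50, 20)
  for (r in seq_len(17)) if (avail[r] < 60) x[r, (avail[r] + 1):60] <- NA
  a <- cronbach_alpha_equalized(x, seed = 4, min_items = 30)
  expect_true(17 %in% a$excluded)              # below min_items
  expect_equal(a$k, 50L)                       # equalized to the smallest kept
  expect_equal(a$n, 16L)
  # the draw is reproducible under the same seed
  b <- cronbach_alpha_equalized(x, seed = 4, min_items = 30)
  expect_identical(a$alpha, b$alpha)
  expect_error(cronbach_alpha_equalized(x), "seed")

  # with zero IQR of the availabilities the lower fence collapses to the
  # mean, so a single deviating subject is dropped rather than equalized to
  avail2 <- matrix(rnorm(10 * 60), 10, 60)
  avail2[1, 41:60] <- NA
  a2 <- cronbach_alpha_equalized(avail2, seed = 5)
  expect_true(1 %in% a2$excluded)
  expect_equal(a2$k, 60L)
})

test_that("split-half Spearman hits its bounds and matches rank-then-Pearson", {
  v <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(split_half_spearman(v, v), 1)
  expect_equal(split_half_spearman(v, -v), -1)
  set.seed(117)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  oracle <- cor(rank(a), rank(b))
  expect_equal(split_half_spearman(a, b), oracle, tolerance = 1e-12)
  expect_true(is.na(split_half_spearman(rep(1, 10), rnorm(10))))
})

test_that("ICC(A,1) equals the mean-squares formula and hits its bounds", {
  set.seed(119)
  # identical columns, subjects differ: perfect agreement
  s <- rnorm(30)
  expect_equal(icc_a1(cbind(s, s, s))$icc, 1, tolerance = 1e-12)
  # brute-force oracle on a random table
  x <- matrix(rnorm(90), 30, 3) + rnorm(30)
  r <- icc_a1(x)
  n <- 30; k <- 3
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(r$icc, oracle, tolerance = 1e-10)
  expect_true(r$lower <= r$icc && r$icc <= r$upper)
})

test_that("an additive occasion shift lowers ICC(A,1) against a consistency ICC", {
  set.seed(121)
  subj <- rnorm(200, 0, 1)
  base <- sapply(1:3, function(i) subj + rnorm(200, 0, 0.3))
  shifted <- base + rep(c(0, 1, 2) * sd(subj), each = 200) * 0
  shifted <- sweep(base, 2, c(0, 1, 0.5))     # occasion shifts of ~1 SD
  icc_abs <- icc_a1(shifted)$icc
  # consistency-type ICC from the same table ignores the column effect
  n <- 200; k <- 3
  grand <- mean(shifted)
  msr <- k * sum((rowMeans(shifted) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(shifted) - grand)^2) / (k - 1)
  mse <- (sum((shifted - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  icc_cons <- (msr - mse) / (msr + (k - 1) * mse)
  expect_lt(icc_abs, icc_cons - 0.05)
})

test_that("RM-ANOVA matches the aov decomposition and base R Mauchly exactly", {
  set.seed(123)
  x <- matrix(rnorm(40 * 3), 40, 3) + rnorm(40)
  an <- rm_anova(x)
  df <- data.frame(y = as.vector(x), s = factor(rep(1:40, 3)),
                   o = factor(rep(1:3, each = 40)))
  sm <- summary(aov(y ~ o + Error(s / o), df))[[2]][[1]]
  expect_equal(an$f, sm[["F value"]][1], tolerance = 1e-10)
  expect_equal(an$p, sm[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(an$eta_p2,
               sm[["Sum Sq"]][1] / sum(sm[["Sum Sq"]]), tolerance = 1e-10)
  mo <- mauchly.test(lm(x ~ 1), X = ~1)
  expect_equal(an$mauchly_p, mo$p.value, tolerance = 1e-10)
  expect_true(an$gg_epsilon >= 0.5 && an$gg_epsilon <= 1)
})

test_that("with two occasions the F statistic is the squared paired t", {
  set.seed(125)
  x <- matrix(rnorm(60), 30, 2) + rnorm(30)
  an <- rm_anova(x)
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(an$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
})

test_that("post hoc tests appear only for significant effects, with Bonferroni and d", {
  set.seed(127)
  base <- matrix(rnorm(150 * 3, sd = 0.4), 150, 3) + rnorm(150)
  x <- sweep(base, 2, c(0, 0.35, 0))           # strong occasion-2 effect
  an <- rm_anova(x)
  expect_lt(an$p_governing, 0.05)
  expect_false(is.null(an$post_hoc))
  expect_equal(nrow(an$post_hoc), 3)
  expect_equal(an$post_hoc$p_bonf, pmin(1, an$post_hoc$p_raw * 3))
  d12 <- mean(x[, 1] - x[, 2]) / sd(x[, 1] - x[, 2])
  expect_equal(an$post_hoc$d[an$post_hoc$pair == "T1 vs T2"], d12,
               tolerance = 1e-12)
  # null data: no post hocs
  an0 <- rm_anova(base)
  expect_null(an0$post_hoc)
})

test_that("alpha converges to the Spearman-Brown value for parallel items", {
  set.seed(129)
  n <- 5000; k <- 10; rho <- 0.4   # per-item reliability
  tr <- rnorm(n)
  items <- sapply(seq_len(k), function(j) {
    sqrt(rho) * tr + sqrt(1 - rho) * rnorm(n)
  })
  a <- cronbach_alpha_equalized(items, seed = 5, min_items = k)
  sb <- k * rho / (1 + (k - 1) * rho)
  expect_equal(a$alpha, sb, tolerance = 0.02)
})
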