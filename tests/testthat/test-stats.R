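test_that("pooled-SD effect sizes reproduce printed group summaries", {
  s <- two_sample_summary(summary1 = list(n = 249, mean = 123.5, sd = 129.4),
                          summary2 = list(n = 149, mean = 209.1, sd = 153.7))
  expect_equal(round(s$cohens_d, 2), -0.62)
  expect_lt(s$p, 0.001)
})

test_that("two-sample summaries handle identical and raw-vector input", {
  x <- c(1, 2, 3, 4)
  s0 <- two_sample_summary(x, x)
  expect_equal(s0$t, 0)
  expect_equal(s0$cohens_d, 0)

  y <- c(2, 4, 5, 7)
  s <- two_sample_summary(x, y)
  # hand-computed pooled formula
  sp <- sqrt(((3) * var(x) + (3) * var(y)) / 6)
  expect_equal(s$cohens_d, (mean(x) - mean(y)) / sp)
  # Welch t agrees with the reference implementation
  tt <- t.test(x, y)
  expect_equal(s$t, unname(tt$statistic))
  expect_equal(s$p, tt$p.value)
  expect_error(two_sample_summary(1, y), "n >= 2")
})

test_that("paired summaries reproduce printed one-sample t statistics", {
  expect_equal(round(paired_summary(mean_diff = -169.6, sd_diff = 408.6,
                                    n = 149)$t, 1), -5.1)
  expect_equal(paired_summary(rep(0, 10))$t, 0)
  d <- c(-1.2, 0.4, 2.2, -0.5, 1.1)
  ps <- paired_summary(d)
  expect_equal(ps$t, mean(d) / (sd(d) / sqrt(5)))
  tt <- t.test(d)
  expect_equal(ps$p, tt$p.value)
})

test_that("exhaustive logistic selection enumerates every subset", {
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(42)
  n <- 120
  dat <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(0.5 * dat$a))
  mt <- exhaustive_logistic(dat, "y", c("a", "b", "c"))
  expect_equal(nrow(mt), 8)
  expect_equal(mt$delta_aic[1], 0)
  expect_equal(sum(mt$weight), 1, tolerance = 1e-9)
  expect_true("(intercept)" %in% mt$model)
  expect_true(any(purrr::map_int(mt$predictors, length) == 3))
  # intercept-only input
  mt0 <- exhaustive_logistic(dat, "y", character(0))
  expect_equal(nrow(mt0), 1)
  expect_equal(mt0$weight, 1)
})

test_that("model AIC matches the reference glm and nesting never lowers
           the log-likelihood", {
  set.seed(7)
  n <- 150
  dat <- data.frame(a = rnorm(n), b = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(1 + dat$a))
  mt <- exhaustive_logistic(dat, "y", c("a", "b"))
  ref <- glm(y ~ a + b, data = dat, family = binomial())
  full_row <- which(purrr::map_int(mt$predictors, length) == 2)
  expect_equal(mt$aic[full_row], AIC(ref), tolerance = 1e-8)
  # adding a predictor cannot decrease lnL
  for (i in seq_len(nrow(mt))) {
    for (j in seq_len(nrow(mt))) {
      if (all(mt$predictors[[i]] %in% mt$predictors[[j]])) {
        expect_lte(mt$logLik[i], mt$logLik[j] + 1e-6)
      }
    }
  }
})

test_that("a strong true predictor appears in every supported model", {
  set.seed(11)
  n <- 400
  dat <- data.frame(w = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(2 * dat$w))
  mt <- exhaustive_logistic(dat, "y", c("w", "n1", "n2", "n3"))
  supported <- mt$predictors[mt$supported]
  expect_true(all(purrr::map_lgl(supported, ~ "w" %in% .x)))
})

test_that("predicted probabilities follow the logistic form", {
  coefs <- c(`(Intercept)` = 0)
  expect_equal(predict_probability(coefs, data.frame()[1, , drop = FALSE]),
               0.5)
  # a printed four-predictor model evaluated at zero covariates
  printed <- c(`(Intercept)` = 2.06, between = -0.001, developed = -3.2,
               grassland = -1.5, wetland = 1.7)
  at0 <- data.frame(between = 0, developed = 0, grassland = 0, wetland = 0)
  expect_equal(predict_probability(printed, at0), plogis(2.06))
  # strictly decreasing in the grassland proportion
  grid <- data.frame(between = 200, developed = 0.1,
                     grassland = seq(0, 1, 0.1), wetland = 0.2)
  p <- predict_probability(printed, grid)
  expect_true(all(diff(p) < 0))
  # numerically stable at extreme linear predictors
  expect_equal(predict_probability(c(`(Intercept)` = 800),
                                   data.frame()[1, , drop = FALSE]), 1)
})

test_that("classification agreement and kappa behave at the extremes and
           match the closed form", {
  labels <- rep(c(1, 0), each = 50)
  perfect <- ifelse(labels == 1, 0.9, 0.1)
  ca <- classification_agreement(perfect, labels)
  expect_equal(ca$kappa, 1)
  expect_equal(ca$pct_correct_hi, 100)
  expect_equal(ca$pct_correct_lo, 100)

  indep <- rep(c(0.9, 0.1), 50)  # independent of labels, balanced
  expect_lt(abs(classification_agreement(indep, labels)$kappa), 0.25)

  # hand-built 2x2 table: a=40 (pred1,lab1), b=10 (pred1,lab0),
  # c=20 (pred0,lab1), d=30 (pred0,lab0)
  probs <- c(rep(0.9, 40), rep(0.9, 10), rep(0.1, 20), rep(0.1, 30))
  labs <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  po <- (40 + 30) / 100
  pe <- (50 * 60 + 50 * 40) / 100^2
  expect_equal(classification_agreement(probs, labs)$kappa,
               (po - pe) / (1 - pe))
})

test_that("Mann-Whitney matches exact enumeration and the reference
           implementation", {
  # identical samples: symmetric, insignificant
  x <- c(1, 2, 3, 4)
  expect_gt(mann_whitney(x, x)$p, 0.6)

  # disjoint supports, n = 8 each: maximal U, exact p
  lo <- 1:8; hi <- 101:108
  mw <- mann_whitney(hi, lo)
  expect_equal(mw$U, 64)
  expect_true(mw$exact)
  expect_equal(mw$p, 2 / choose(16, 8))

  # U(x, y) + U(y, x) = n1 n2
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(9)
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 63)
  }

  # agreement with wilcox.test over all partitions at n1 = n2 = 3
  pool <- c(1.2, 3.4, 0.7, 2.2, 5.1, 4.4)
  idx <- utils::combn(6, 3)
  for (j in seq_len(ncol(idx))) {
    x <- pool[idx[, j]]; y <- pool[-idx[, j]]
    mw <- mann_whitney(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
  }

  # tie-corrected z agrees with the large-sample reference
  set.seed(9)
  a <- sample(1:5, 40, replace = TRUE)
  b <- sample(2:6, 45, replace = TRUE)
  mw <- mann_whitney(a, b)
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
})
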