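test_that("paired t-test handles boundary and degenerate cases", {
  x <- c(430, 450, 470, 440, 455)
  r <- paired_qtc_test(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  expect_error(paired_qtc_test(x, x + 25), class = "degenerate_test")
  expect_error(paired_qtc_test(x, x[-1]), class = "invalid_parameter")
  # agrees with stats::t.test on a regular case
  set.seed(1)
  a <- rnorm(30, 500, 50); b <- rnorm(30, 430, 50)
  r2 <- paired_qtc_test(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
})

test_that("a programmed admission-to-peak shift is reliably detected", {
  set.seed(2)
  reject <- vapply(1:50, function(i) {
    adm <- rnorm(50, 435, 40)
    peak <- adm + 70 + rnorm(50, 0, 40)
    paired_qtc_test(peak, adm)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.98)
})

test_that("Spearman matches the rank-then-Pearson oracle and is monotone-invariant", {
  x <- c(1, 3, 2, 8, 5, 4)
  expect_equal(spearman_cor(x, exp(x))$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)
  set.seed(3)
  for (k in 1:20) {
    a <- sample(1:6, 12, replace = TRUE)   # ties exercised
    b <- rnorm(12)
    expect_equal(spearman_cor(a, b)$r, spearman_oracle(a, b))
    # invariance under a strictly monotone transform
    expect_equal(spearman_cor(a, b)$r, spearman_cor(a, exp(b / 2))$r)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)),
               class = "undefined_correlation")
})

test_that("univariate screen keeps signal and drops nothing it shouldn't", {
  set.seed(4)
  d <- data.frame(y = rnorm(80))
  d$same <- d$y                       # candidate equal to the outcome
  d$noise <- rnorm(80)
  sc <- suppressWarnings(
    univariate_screen(d, "y", c("same", "noise"), type = "linear"))
  expect_true(sc$selected[sc$variable == "same"])
  sc0 <- univariate_screen(d, "y", character(0), type = "linear")
  expect_equal(nrow(sc0), 0)
  d$holey <- d$noise; d$holey[1:3] <- NA
  expect_message(univariate_screen(d, "y", "holey", type = "linear"),
                 "3 row")
})

test_that("log-LGE regression recovers exact fits and flags collinearity", {
  set.seed(5)
  d <- data.frame(delta = rnorm(40, 70, 30))
  d$lge_g <- exp(1.7 + 0.01 * d$delta)           # noise-free
  fit <- suppressWarnings(fit_linear_log_lge(d, "delta"))
  expect_equal(fit$r2, 1)
  expect_equal(fit$coefficients$estimate[2], 0.01, tolerance = 1e-8)
  d$delta2 <- d$delta
  expect_error(suppressWarnings(fit_linear_log_lge(d, c("delta", "delta2"))),
               class = "rank_deficient")
  d$lge_g[1:4] <- 0
  expect_message(suppressWarnings(fit_linear_log_lge(d, "delta")), "zero LGE")
})

test_that("logistic salvage model reports ORs, flags separation, needs 2 classes", {
  set.seed(6)
  t <- simulate_cohort(n = 200, seed = 6)$table
  fit <- fit_logistic_msi(t, c("delta_ma_day6", "lvef_pct"))
  expect_s3_class(fit, "model_result")
  or <- fit$coefficients$estimate[fit$coefficients$term == "delta_ma_day6"]
  expect_gt(or, 1)   # higher dispersion, higher odds of poor salvage
  # CI brackets the point estimate
  co <- fit$coefficients
  expect_true(all(co$ci_lo <= co$estimate & co$estimate <= co$ci_hi))

  d <- data.frame(msi = c(rep(0.2, 10), rep(0.9, 10)),
                  x = c(rnorm(10, -5), rnorm(10, 5)))  # separable
  sep <- fit_logistic_msi(d, "x")
  expect_true(sep$separated)
  expect_null(sep$coefficients)

  d1 <- data.frame(msi = rep(0.2, 20), x = rnorm(20))
  expect_error(fit_logistic_msi(d1, "x"), class = "one_class")
})

test_that("null covariates keep ~95% CI coverage of OR = 1", {
  set.seed(7)
  cover <- vapply(1:100, function(i) {
    d <- data.frame(msi = runif(120), x = rnorm(120))
    fit <- fit_logistic_msi(d, "x")
    if (fit$separated) return(NA)
    co <- fit$coefficients[fit$coefficients$term == "x", ]
    co$ci_lo <= 1 && 1 <= co$ci_hi
  }, logical(1))
  expect_gt(mean(cover, na.rm = TRUE), 0.88)
})

test_that("ROC/Youden equals exhaustive enumeration and the U statistic", {
  # printed toy: 6 scores, the enumeration oracle must agree exactly
  sc <- c(1, 2, 3, 4, 5, 6); y <- c(0, 0, 1, 0, 1, 1)
  r <- roc_youden(sc, y)
  o <- roc_oracle(sc, y)
  expect_equal(r$auc, o$auc)
  expect_equal(r$cutoff, o$cutoff)
  expect_equal(r$youden, o$j)

  # perfect separation
  rp <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(rp$auc, 1); expect_equal(rp$youden, 1)

  # random instances with ties: AUC == rescaled Mann-Whitney, Youden ==
  # brute-force maximizer
  set.seed(8)
  for (k in 1:20) {
    s <- sample(1:8, 30, replace = TRUE)
    yy <- rbinom(30, 1, 0.4)
    if (length(unique(yy)) < 2) next
    r <- roc_youden(s, yy)
    expect_equal(r$auc, auc_mann_whitney(s, yy))
    o <- roc_oracle(s, yy)
    expect_equal(r$cutoff, o$cutoff)
    expect_equal(r$youden, o$j)
  }
  expect_error(roc_youden(rnorm(5), rep(1, 5)), class = "one_class")
})

test_that("ROC agrees with pROC on a non-trivial instance", {
  set.seed(9)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(1.5 * s))
  r <- roc_youden(s, y)
  pr <- pROC::roc(y, s, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("an uninformative score has AUC near one half", {
  set.seed(10)
  s <- rnorm(1000); y <- rbinom(1000, 1, 0.5)
  expect_lt(abs(roc_youden(s, y)$auc - 0.5), 0.05)
})

test_that("Youden ties break toward higher specificity", {
  # two thresholds reach the same J; the rule must report the one with
  # higher specificity
  s <- c(1, 2, 3, 4); y <- c(0, 1, 0, 1)
  r <- roc_youden(s, y)
  j <- r$sensitivity + r$specificity - 1
  best <- which(abs(j - max(j)) < 1e-12)
  expect_equal(r$specificity_at_cutoff, max(r$specificity[best]))
})

test_that("Cohen's kappa matches its definition and the e1071 cross-check", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  expect_equal(cohen_kappa(c("+", "+", "-", "-"),
                           c("+", "-", "+", "-"))$kappa, 0)
  expect_error(cohen_kappa(rep("x", 4), rep("x", 4)),
               class = "undefined_kappa")
  set.seed(11)
  a <- sample(letters[1:3], 300, replace = TRUE)
  b <- sample(letters[1:3], 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  k <- cohen_kappa(a, b)
  expect_lt(abs(k$kappa), 0.15)   # independent raters: near zero
  e <- e1071::classAgreement(table(a, b))
  expect_equal(k$kappa, e$kappa)
})
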