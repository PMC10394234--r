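# Statistics layer against closed-form and brute-force oracles.

test_that("one-way ANOVA matches the hand decomposition and formula oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_oneway(v, g)
  expect_equal(res$F, 3)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))
  # identical group means, nonzero within-variance
  res0 <- anova_oneway(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(res0$F, 0)
  # brute-force sums-of-squares oracle on random data
  set.seed(2)
  for (rep in 1:10) {
    vv <- rnorm(30)
    gg <- sample(c("x", "y", "z"), 30, replace = TRUE)
    if (min(table(gg)) < 2) next
    m <- mean(vv)
    ssb <- sum(tapply(vv, gg, function(x) length(x) * (mean(x) - m)^2))
    ssw <- sum(tapply(vv, gg, function(x) sum((x - mean(x))^2)))
    k <- length(unique(gg))
    Fo <- (ssb / (k - 1)) / (ssw / (30 - k))
    expect_equal(anova_oneway(vv, gg)$F, Fo, tolerance = 1e-10)
  }
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(anova_oneway(1:4, rep("a", 4)), "two groups")
})

test_that("Bonferroni post-hoc multiplies pooled-t p values by the pair count", {
  set.seed(5)
  v <- rnorm(40)
  g <- rep(c("a", "b", "c", "d"), each = 10)
  ph <- bonferroni_posthoc(v, g)
  expect_identical(nrow(ph), 6L)
  for (i in seq_len(6)) {
    a <- v[g == ph$group_a[i]]; b <- v[g == ph$group_b[i]]
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(ph$p_raw[i], tt$p.value, tolerance = 1e-12)
    expect_equal(ph$p_adjusted[i], min(1, tt$p.value * 6))
    expect_equal(ph$direction[i], sign(mean(a) - mean(b)))
  }
  # raw 0.01 with 6 pairs -> 0.06 (arithmetic of the correction)
  expect_equal(min(1, 0.01 * 6), 0.06)
  # identical groups: adjusted p = 1, direction 0
  v2 <- c(rnorm(5), rnorm(5))
  v2[6:10] <- v2[1:5]
  ph2 <- bonferroni_posthoc(v2, rep(c("a", "b"), each = 5))
  expect_equal(ph2$p_adjusted, 1)
  expect_equal(ph2$direction, 0)
})

test_that("correlation matrix matches hand computations and flags degeneracies", {
  cm <- correlation_matrix(data.frame(x = c(1, 2, 3), y = c(2, 4, 6)))
  expect_equal(cm$r["x", "y"], 1)
  cm2 <- correlation_matrix(data.frame(x = c(1, 2, 3), y = c(6, 4, 5)))
  expect_equal(cm2$r["x", "y"], -0.5, tolerance = 1e-12)
  expect_equal(diag(cm2$r), c(x = 1, y = 1))
  expect_true(isSymmetric(cm2$r))
  # point-biserial via 0/1 coding of a two-level factor
  df <- data.frame(sex = c("male", "female", "male", "female", "male"),
                   v = c(3, 1, 4, 2, 5))
  cm3 <- correlation_matrix(df)
  expect_equal(cm3$r["sex", "v"],
               cor(c(1, 0, 1, 0, 1), df$v), tolerance = 1e-12)
  # zero-variance column flagged, not an error
  cm4 <- correlation_matrix(data.frame(x = c(1, 1, 1), y = c(1, 2, 3)))
  expect_true(cm4$flagged["x", "y"])
  expect_true(is.na(cm4$r["x", "y"]))
  expect_error(correlation_matrix(data.frame(x = 1:2, y = 2:1)),
               ">= 3 complete")
})

test_that("predictor preparation inverse codes and z-standardizes", {
  set.seed(10)
  tab <- data.frame(src = rnorm(40, 10, 3), age = rnorm(40, 20, 5),
                    sex = sample(c("male", "female"), 40, replace = TRUE))
  out <- prepare_regression_predictors(tab, c("src", "age", "sex"),
                                       invert = "src")
  expect_lt(abs(mean(out$src)), 1e-12)
  expect_equal(sd(out$src), 1, tolerance = 1e-12)
  expect_lt(abs(mean(out$age)), 1e-12)
  expect_setequal(unique(out$sex), c(0, 1))
  # inverse coding flips the correlation sign with any covariate
  expect_equal(cor(out$src, tab$age), -cor(tab$src, tab$age),
               tolerance = 1e-12)
  # standardization is idempotent
  out2 <- prepare_regression_predictors(out, c("src", "age"))
  expect_equal(out2$src, out$src, tolerance = 1e-12)
  expect_error(prepare_regression_predictors(
    data.frame(z = rep(1, 5)), "z"), "zero-variance")
})

test_that("logistic models recover the 2x2 cross-product odds ratio", {
  # exposed: 10 events / 10 non-events; unexposed: 5 events / 15 non-events
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15))
  x <- c(rep(1, 20), rep(0, 20))
  fit <- fit_logistic(y, data.frame(exposure = x), "unadjusted")
  expect_equal(fit$or, (10 * 15) / (10 * 5) / 1, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(fit$ci_lo < fit$or && fit$or < fit$ci_hi)
})

test_that("null predictors give OR near 1 with covering confidence intervals", {
  set.seed(14)
  y <- rbinom(2000, 1, 0.3)
  x <- rnorm(2000)
  fit <- fit_logistic(y, data.frame(x = x), "unadjusted")
  expect_lt(abs(log(fit$or)), 0.15)
  expect_true(fit$ci_lo < 1 && fit$ci_hi > 1)
})

test_that("degenerate outcomes and separation are reported as errors", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_error(fit_logistic(rep(1, 20), data.frame(x = rnorm(20))),
               "single class")
  expect_error(fit_logistic(y, data.frame(x = y), "unadjusted"),
               "did not converge")
  rep_fit <- fit_logistic(y, data.frame(x = y), "unadjusted",
                          on_separation = "report")
  expect_false(rep_fit$converged)
  expect_true(is.na(rep_fit$or))
})

test_that("adjusted mode fits one joint model over all predictors", {
  set.seed(20)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1))
  fit <- fit_logistic(y, data.frame(x1 = x1, x2 = x2), "adjusted")
  expect_identical(nrow(fit), 2L)
  expect_identical(unique(fit$model), "adjusted")
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(log(fit$or), unname(coef(ref)[-1]), tolerance = 1e-8)
})
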