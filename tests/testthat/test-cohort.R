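# Derived quantities, group comparisons against enumeration/simulation
# oracles, and OLS fitting against the normal equations.

test_that("lesion/fellow ratio arithmetic", {
  expect_equal(compute_lf_ratio(180, 200), 0.90)
  expect_equal(compute_lf_ratio(205, 205), 1.0)
  # ratio of the reported OP group means (not the mean of ratios)
  expect_equal(round(compute_lf_ratio(196.9, 211.7), 3), 0.930)
  expect_error(compute_lf_ratio(180, 0), "positive")
})

test_that("acuity conversion to LogMAR", {
  expect_equal(snellen_to_logmar("20/20"), 0)
  expect_equal(snellen_to_logmar("20/200"), 1)
  expect_equal(snellen_to_logmar("20/40"), log10(2))
  expect_equal(snellen_to_logmar(0.5), log10(2))
  expect_equal(snellen_to_logmar("6/12"), log10(2))
  expect_equal(snellen_to_logmar("CF"), 2.0)
  expect_equal(snellen_to_logmar(c("20/20", "20/200")), c(0, 1))
  expect_error(snellen_to_logmar(0), "positive")
  expect_error(snellen_to_logmar("blurry"), "lookup")
})

test_that("disc swelling classification uses the inclusive 10% boundary", {
  expect_equal(classify_group(136, 100), "OP")
  expect_equal(classify_group(100, 100), "RN")
  expect_equal(classify_group(110, 100), "OP")       # boundary inclusive
  expect_equal(classify_group(109.9, 100), "RN")
  expect_equal(classify_group(c(136, 94), c(100, 100)), c("OP", "RN"))
  # configurable boundary
  expect_equal(classify_group(109, 100, threshold = 1.09), "OP")
})

test_that("two-sample comparisons: identical groups, pooled t, Fisher oracle", {
  d <- data.frame(group = rep(c("OP", "RN"), each = 10L),
                  flag = rep(rep(c(TRUE, FALSE), c(3L, 7L)), 2L),
                  val = rep(1, 20L))
  expect_equal(compare_groups(d, "flag", "exact")$p_value, 1)

  set.seed(5)
  d2 <- data.frame(group = rep(c("OP", "RN"), c(12L, 15L)),
                   val = rnorm(27L, rep(c(0, 1), c(12L, 15L))))
  ht <- compare_groups(d2, "val", "t_test")
  ref <- t.test(val ~ group, data = d2, var.equal = TRUE)
  expect_equal(ht$p_value, ref$p.value)

  # Fisher two-sided p against full hypergeometric enumeration
  d3 <- data.frame(group = rep(c("OP", "RN"), each = 10L),
                   flag = c(rep(c(TRUE, FALSE), c(3L, 7L)),
                            rep(c(TRUE, FALSE), c(8L, 2L))))
  p_pkg <- compare_groups(d3, "flag", "exact")$p_value
  # margins: rows (FALSE, TRUE) x cols (OP, RN); enumerate a = #TRUE in OP
  a_obs <- 3L; r1 <- 10L; r2 <- 10L; c1 <- 11L
  probs <- dhyper(max(0L, c1 - r2):min(r1, c1), r1, r2, c1)
  names(probs) <- max(0L, c1 - r2):min(r1, c1)
  p_enum <- sum(probs[probs <= probs[as.character(a_obs)] * (1 + 1e-7)])
  expect_equal(p_pkg, p_enum, tolerance = 1e-10)

  expect_error(compare_groups(d, "val", "t_test"),
               class = "pctopo_stats_error")  # zero variance in both groups
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(314)
  ps <- replicate(400, {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 30L),
                    val = rnorm(90L))
    compare_groups(d, "val", "anova")$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("OLS matches the normal equations and recovers noiseless data", {
  # 6-row hand table against an explicit normal-equations solve
  d <- data.frame(y = c(3.1, 4.9, 7.2, 8.8, 11.1, 12.9),
                  x1 = c(1, 2, 3, 4, 5, 6),
                  x2 = c(0.5, -0.2, 0.7, -0.4, 0.1, 0.3))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  r <- fit_regression(d, "y", c("x1", "x2"))
  expect_equal(r$intercept, beta[1L], tolerance = 1e-10)
  expect_equal(r$terms$estimate, beta[2:3, 1L], tolerance = 1e-10)
  expect_equal(r$n_used, 6L)

  # noiseless outcome: exact recovery, R-square 1
  set.seed(21)
  d2 <- data.frame(x1 = rnorm(40), x2 = runif(40))
  d2$y <- 2 - 0.7 * d2$x1 + 1.3 * d2$x2
  r2 <- suppressWarnings(fit_regression(d2, "y", c("x1", "x2")))
  expect_equal(r2$terms$estimate, c(-0.7, 1.3), tolerance = 1e-10)
  expect_equal(r2$r_square, 1, tolerance = 1e-12)

  # listwise deletion reported through n_used
  d2$x1[3L] <- NA
  expect_equal(
    suppressWarnings(fit_regression(d2, "y", c("x1", "x2")))$n_used, 39L)

  # rank deficiency names the collinear term
  d2$x3 <- d2$x2 * 2
  expect_error(fit_regression(d2, "y", c("x2", "x3")), "x3")
})

test_that("centering covariates changes only the intercept", {
  set.seed(8)
  d <- data.frame(x1 = rnorm(60, 5), x2 = runif(60, 10, 20))
  d$y <- 1 + 0.5 * d$x1 - 0.2 * d$x2 + rnorm(60, 0, 0.3)
  r <- fit_regression(d, "y", c("x1", "x2"))
  dc <- transform(d, x1 = x1 - mean(x1), x2 = x2 - mean(x2))
  rc <- fit_regression(dc, "y", c("x1", "x2"))
  expect_equal(rc$terms$estimate, r$terms$estimate, tolerance = 1e-12)
  expect_equal(rc$intercept, mean(d$y), tolerance = 1e-12)
})

test_that("estimates converge to truth on simulated data", {
  set.seed(1234)
  n <- 10000L
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1L, 0.4))
  d$y <- 0.8 - 0.45 * d$x1 + 0.25 * d$x2 + rnorm(n, 0, 0.5)
  r <- fit_regression(d, "y", c("x1", "x2"))
  se <- summary(r$fit)$coefficients[-1L, 2L]
  expect_true(all(abs(r$terms$estimate - c(-0.45, 0.25)) < 2 * se))
})

test_that("univariate screening carries forward significant candidates plus forced terms", {
  set.seed(77)
  n <- 200L
  d <- data.frame(age = rnorm(n, 40, 10),
                  gender = sample(c("M", "F"), n, replace = TRUE),
                  strong = rnorm(n), weak = rnorm(n))
  d$y <- 0.5 * d$strong + rnorm(n)
  r <- screen_then_fit(d, "y", c("strong", "weak"))
  expect_true(r$screen$selected[r$screen$candidate == "strong"])
  expect_false(r$screen$selected[r$screen$candidate == "weak"])
  expect_setequal(r$terms$term, c("strong", "age", "genderM"))

  # nothing survives: forced-only model with a warning
  d$y2 <- rnorm(n)
  expect_warning(r2 <- screen_then_fit(d, "y2", "weak"), "forced")
  expect_setequal(r2$terms$term, c("age", "genderM"))
})

test_that("the published prediction equation evaluates exactly", {
  expect_equal(predict_pct_ratio(0, FALSE, 0, 0, FALSE), 1.1398,
               tolerance = 1e-12)
  expect_equal(predict_pct_ratio(1, FALSE, 0, 0, FALSE), 0.9098,
               tolerance = 1e-12)
  want <- 1.1398 - 0.230 * 1.36 - 0.0674 - 0.017 * (-2.07) +
    0.002 * 37 + 0.001
  expect_equal(predict_pct_ratio(1.36, TRUE, -2.07, 37, TRUE), want,
               tolerance = 1e-12)
  expect_equal(round(want, 4), 0.8698)

  # affine: prediction differences equal coefficient times delta
  b <- pct_ratio_coefficients()
  d1 <- predict_pct_ratio(1.5, TRUE, -2, 40, FALSE) -
    predict_pct_ratio(1.1, TRUE, -2, 40, FALSE)
  expect_equal(d1, b[["rnfl_ratio"]] * 0.4, tolerance = 1e-12)
  d2 <- predict_pct_ratio(1, FALSE, 0, 55, TRUE) -
    predict_pct_ratio(1, FALSE, 0, 30, TRUE)
  expect_equal(d2, b[["age"]] * 25, tolerance = 1e-12)
})
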