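test_that("published summary statistics are recovered from group tables", {
  # empathy quotient row: 16.06 +/- 9.98 (n 16) vs 19.74 +/- 11.02 (n 23)
  eq <- pooled_t_from_summary(16, 16.06, 9.98, 23, 19.74, 11.02)
  expect_equal(eq$df, 37)
  expect_equal(round(eq$statistic, 3), -1.065)
  expect_equal(round(eq$cohens_d, 3), -0.347)
  # verbal IQ row
  iq <- pooled_t_from_summary(16, 103.19, 19.48, 23, 105.35, 11.33)
  expect_equal(round(iq$statistic, 3), -0.437)
  # equal means give t = 0 and d = 0
  z <- pooled_t_from_summary(10, 5, 1, 12, 5, 2)
  expect_equal(z$statistic, 0)
  expect_equal(cohens_d(10, 5, 1, 12, 5, 2), 0)
  # d = 1 when the mean difference equals the pooled SD
  expect_equal(cohens_d(20, 6, 1, 20, 5, 1), 1)
})

test_that("raw-sample pooled t agrees with its summary form and stats::t.test", {
  for (seed in 1:6) {
    set.seed(seed)
    a <- rnorm(9 + seed, 1, 2); b <- rnorm(14, 0.5, 1.5)
    raw <- pooled_t(a, b)
    summ <- pooled_t_from_summary(length(a), mean(a), sd(a),
                                  length(b), mean(b), sd(b))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$p, summ$p, tolerance = 1e-12)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
    expect_equal(raw$df, unname(ref$parameter))
  }
  expect_error(pooled_t(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(pooled_t_from_summary(1, 0, 1, 5, 0, 1), "n >= 2")
})

test_that("swapping the groups negates t and d and reflects U", {
  set.seed(10)
  a <- rnorm(8); b <- rnorm(11, 0.3)
  t_ab <- pooled_t(a, b); t_ba <- pooled_t(b, a)
  expect_equal(t_ab$statistic, -t_ba$statistic, tolerance = 1e-12)
  expect_equal(t_ab$cohens_d, -t_ba$cohens_d, tolerance = 1e-12)
  u_ab <- mann_whitney(a, b); u_ba <- mann_whitney(b, a)
  expect_equal(u_ab$statistic, length(a) * length(b) - u_ba$statistic)
  expect_equal(u_ab$p, u_ba$p, tolerance = 1e-12)  # two-sided p unchanged
})

test_that("Mann-Whitney U and its exact p match brute-force enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  # identical multisets sit at the midpoint
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  for (seed in 1:8) {
    set.seed(seed)
    a <- sample(1:6, 4, replace = TRUE)  # ties likely
    b <- sample(1:6, 5, replace = TRUE)
    res <- mann_whitney(a, b, "greater")
    expect_equal(res$statistic, naive_u(a, b))
    expect_equal(res$p, naive_u_p_greater(a, b), tolerance = 1e-12)
  }
  # tie-free exact p agrees with the reference implementation
  for (seed in 1:5) {
    set.seed(seed + 100)
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mann_whitney(a, b, "two.sided")$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("large-sample Mann-Whitney uses the tie-corrected approximation", {
  set.seed(3)
  a <- round(rnorm(20, 0, 2)); b <- round(rnorm(25, 0.8, 2))
  res <- mann_whitney(a, b, "two.sided")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("Shapiro-Wilk wrapper reproduces the reference behaviour", {
  set.seed(5)
  x <- rnorm(50)
  sw <- shapiro_wilk(x)
  expect_gt(sw$W, 0.9)
  expect_equal(sw$W, unname(shapiro.test(x)$statistic))
  skewed <- exp(rnorm(50))
  expect_lt(shapiro_wilk(skewed)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("the normality gate picks the test the data allow", {
  set.seed(6)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  expect_equal(compare_groups(a, b)$test, "student_t")
  expect_equal(compare_groups(exp(rnorm(20, 0, 1.5)), b)$test, "mann_whitney")
})

test_that("both gated tests hold their nominal level under the null", {
  set.seed(7)
  n_sim <- 2000
  rej <- matrix(FALSE, n_sim, 2)
  for (i in seq_len(n_sim)) {
    a <- rnorm(16); b <- rnorm(23)
    rej[i, 1] <- pooled_t(a, b)$p < 0.05
    rej[i, 2] <- mann_whitney(a, b)$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) < 0.02))
})

test_that("group-mean imputation fills gaps without moving the means", {
  df <- data.frame(dyad_id = paste0("d", 1:6),
                   group = rep(c("g1", "g2"), each = 3),
                   adc = c(10, 20, NA, 5, NA, 15))
  out <- impute_group_mean(df, "adc")
  expect_equal(out$adc, c(10, 20, 15, 5, 10, 15))
  expect_equal(out$adc_imputed, c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(mean(out$adc[out$group == "g1"]), mean(c(10, 20), na.rm = TRUE))
  # nothing missing: identity apart from the flag column
  out2 <- impute_group_mean(out[, 1:3], "adc")
  expect_equal(out2$adc, out$adc)
  df_bad <- data.frame(group = c("g1", "g2"), adc = c(NA, 3))
  expect_error(impute_group_mean(df_bad, "adc"), "no observed values")
})

test_that("score correlations behave at their fixed points", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expect_equal(correlate_scores(x, x)$estimate, 1)
  expect_equal(correlate_scores(x, -x)$estimate, -1)
  expect_equal(correlate_scores(x, 2 * x + 1, method = "pearson")$estimate, 1)
  set.seed(8)
  indep <- correlate_scores(rnorm(100), rnorm(100))
  expect_lt(abs(indep$estimate), 0.3)
  expect_error(correlate_scores(rep(1, 5), 1:5), "constant")
  expect_error(correlate_scores(1:2, 2:1), "3 complete pairs")
})
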