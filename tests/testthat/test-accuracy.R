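test_that("summary-statistic t-test reproduces the hand-computed pooled t", {
  # (7.28 +/- 0.32, n 10) vs (7.86 +/- 0.27, n 10):
  # sp^2 = 0.08765, se = 0.132401, t = 4.380635
  out <- compare_from_summary(7.28, 0.32, 10, 7.86, 0.27, 10)
  expect_equal(out$mean_diff, 0.58, tolerance = 1e-12)
  expect_equal(out$t_stat, 4.380635, tolerance = 1e-6)
  expect_lt(out$p_value, 0.001)
  expect_identical(out$category, "very highly significant")
  expect_identical(out$df, 18)
})

test_that("raw and summary routes agree, and both match stats::t.test", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = 6, sd = 0.4)
    y <- rnorm(sample(3:12, 1), mean = 6.4, sd = 0.6)
    cg <- compare_group(x, y)
    cs <- compare_from_summary(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y))
    expect_equal(cg$t_stat, cs$t_stat, tolerance = 1e-12)
    expect_equal(cg$p_value, cs$p_value, tolerance = 1e-12)
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(cs$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(cs$p_value, tt$p.value, tolerance = 1e-10)
    tw <- t.test(y, x)
    cw <- compare_from_summary(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y), var_equal = FALSE)
    expect_equal(cw$t_stat, unname(tw$statistic), tolerance = 1e-10)
    expect_equal(cw$p_value, tw$p.value, tolerance = 1e-10)
  }
})

test_that("swapping the samples negates t and mean_diff, keeps p", {
  a <- compare_from_summary(5.2, 0.4, 8, 5.9, 0.7, 11)
  b <- compare_from_summary(5.9, 0.7, 11, 5.2, 0.4, 8)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$p_value, b$p_value)
})

test_that("degenerate variances are handled without division by zero", {
  same <- compare_group(c(6, 6, 6), c(6, 6, 6))
  expect_identical(c(same$mean_diff, same$t_stat, same$p_value), c(0, 0, 1))
  expect_identical(same$category, "non-significant")

  one_flat <- compare_group(c(6, 6, 6, 6), c(6.2, 6.5, 6.1, 6.9))
  expect_true(is.finite(one_flat$t_stat))
  expect_true(one_flat$p_value > 0 && one_flat$p_value <= 1)

  flat_diff <- compare_from_summary(6, 0, 5, 7, 0, 5)
  expect_true(flat_diff$degenerate)
  expect_identical(flat_diff$p_value, 0)

  expect_error(compare_from_summary(6, 0.5, 1, 7, 0.5, 5),
               class = "insufficient_data")
  solo <- compare_group(6.1, c(6.0, 6.3))
  expect_identical(solo$n, 2L)
  expect_true(is.na(solo$p_value))
})

test_that("p-value categories follow the reporting convention, monotonely", {
  expect_identical(classify_p(c(0.05, 0.049, 0.005, 0.0005)),
                   c("non-significant", "significant", "highly significant",
                     "very highly significant"))
  expect_identical(classify_p(1), "non-significant")
  expect_error(classify_p(1.2), class = "invalid_p")
  strength <- c("non-significant" = 0, "significant" = 1,
                "highly significant" = 2, "very highly significant" = 3)
  p_grid <- sort(c(10^seq(-5, 0, by = 0.25), 0.05, 0.01, 0.001))
  expect_true(all(diff(strength[classify_p(p_grid)]) <= 0))
})

test_that("bias regression matches the closed-form normal equations", {
  flat <- bias_regression(c(3, 5, 7, 9), rep(0.4, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.4, tolerance = 1e-12)

  ca <- c(3.2, 4.8, 6.1, 7.7, 9.4)
  lin <- 0.8 - 0.05 * ca
  exact <- bias_regression(ca, lin)
  expect_equal(exact$slope, -0.05, tolerance = 1e-12)
  expect_equal(exact$intercept, 0.8, tolerance = 1e-12)

  set.seed(31)
  x <- runif(40, 3, 11)
  d <- 0.6 - 0.03 * x + rnorm(40, 0, 0.2)
  fit <- bias_regression(x, d)
  # brute-force normal equations
  sl <- (sum(x * d) - length(x) * mean(x) * mean(d)) /
        (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit$slope, sl, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(d) - sl * mean(x), tolerance = 1e-10)
  expect_equal(fit$overall_mean_diff, mean(d))
  expect_equal(fit$overall_sd, sd(d))

  expect_error(bias_regression(rep(6, 4), d[1:4]), class = "undefined_slope")
})

test_that("published per-group summaries are internally consistent", {
  ref <- reference_group_summary()
  recomputed <- ref$eda_mean - ref$ca_mean
  two_dp <- ref$eda_dp == 2
  expect_identical(sum(two_dp), 12L)
  expect_true(all(abs(recomputed[two_dp] - ref$mean_diff[two_dp]) <= 0.01 + 1e-9))
  # the 1-dp male rows: two are consistent, two carry a known misprint
  one_dp <- !two_dp
  expect_true(all(abs(recomputed[one_dp] - ref$mean_diff[one_dp]) <= 0.1))
  # printed p-values are reproduced from the printed summaries; they track
  # the unequal-variance (Welch) test, as expected when EDA SDs dwarf CA SDs
  for (i in which(ref$p_printed != "<0.001" & ref$eda_dp == 2)) {
    p <- compare_from_summary(ref$ca_mean[i], ref$ca_sd[i], ref$n[i],
                              ref$eda_mean[i], ref$eda_sd[i], ref$n[i],
                              var_equal = FALSE)$p_value
    expect_lt(abs(p - as.numeric(ref$p_printed[i])), 0.03,
              label = sprintf("row %d |p - printed|", i))
  }
})

test_that("stratified accuracy table covers every populated cell", {
  cohort <- generate_cohort(small_config(), score_tab, conv_tab)
  est <- estimate_cohort(score_cohort(cohort, score_tab)$cohort, conv_tab)
  tab <- accuracy_table(est)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(tab$n), nrow(est))
  expect_equal(tab$mean_diff, tab$eda_mean - tab$ca_mean, tolerance = 1e-12)
})
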