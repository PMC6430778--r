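test_that("noiseless pairs recover the generating model to 1e-6", {
  for (m in default_prediction_models()) {
    dms <- seq(5, 98, length.out = 50)
    attr(dms, "sex") <- m$sex
    ca <- predict_age(dms, m)
    free <- fit_logistic_growth(dms, ca, asymptote = "free")
    expect_true(free$converged)
    expect_equal(free$model$a, m$a, tolerance = 1e-6)
    expect_equal(free$model$b, m$b, tolerance = 1e-6)
    expect_equal(free$model$c, m$c, tolerance = 1e-6)
    expect_equal(free$r_squared, 1, tolerance = 1e-9)
    # linearised fit with the true asymptote agrees with the free fit
    lin <- fit_logistic_growth(dms, ca, asymptote = 1 / m$a)
    expect_equal(lin$model$b, free$model$b, tolerance = 1e-6)
    expect_equal(lin$model$c, free$model$c, tolerance = 1e-6)
  }
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_logistic_growth(c(10, 20, 30), rep(5, 3)),
               class = "degenerate_response")
  expect_error(fit_logistic_growth(c(10, 10, 10), c(4, 5, 6)),
               class = "insufficient_data")
  expect_error(fit_logistic_growth(c(10, 20, 30), c(4, -5, 6)),
               class = "invalid_input")
  expect_error(fit_logistic_growth(c(10, 20, 30), c(4, 5, 13), asymptote = 12),
               class = "invalid_asymptote")
})

test_that("fits on age-increasing data keep the decay base inside (0, 1)", {
  set.seed(41)
  for (i in 1:5) {
    pairs <- simulate_model_pairs(40, default_prediction_models()$M,
                                  noise_sd = 0.4)
    fit <- fit_logistic_growth(pairs$dms, pairs$ca)
    expect_true(fit$model$c > 0 && fit$model$c < 1)
  }
})

test_that("noisy calibration recovers the decay base across seeds", {
  # n = 74 pairs, 0.3-year age noise: c-hat within 0.01 in >= 9 of 10 seeds
  m <- default_prediction_models()$M
  hits <- sum(vapply(1:10, function(s) {
    pairs <- simulate_model_pairs(74, m, noise_sd = 0.3, seed = 1000 + s)
    abs(fit_logistic_growth(pairs$dms, pairs$ca)$model$c - m$c) <= 0.01
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("the fitted model beats fixed candidates on its own data", {
  set.seed(43)
  pairs <- simulate_model_pairs(60, default_prediction_models()$M,
                                noise_sd = 0.3)
  fit <- fit_logistic_growth(pairs$dms, pairs$ca)
  grid <- expand.grid(a = c(0.075, 0.083, 0.09), b = c(0.3, 0.351, 0.4),
                      c = c(0.96, 0.969, 0.975))
  for (i in seq_len(nrow(grid))) {
    cand <- prediction_model("M", grid$a[i], grid$b[i], grid$c[i])
    expect_gte(fit$r_squared + 1e-12,
               r_squared(cand, pairs$dms, pairs$ca))
  }
})

test_that("spearman matches rank-then-pearson on ties and cor.test exactly", {
  expect_equal(spearman(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman(1:8, -(1:8))$rho, -1)

  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  # brute-force Pearson on mid-ranks, written out from the sums
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  expect_equal(spearman(x, y)$rho, num / den, tolerance = 1e-12)
  expect_equal(spearman(x, y)$rho,
               unname(suppressWarnings(
                 cor.test(x, y, method = "spearman")$estimate)),
               tolerance = 1e-12)

  expect_error(spearman(rep(1, 5), 1:5), class = "undefined_correlation")
})

test_that("exact permutation p-value agrees with cor.test for small n", {
  set.seed(44)
  x <- c(3.1, 1.2, 5.4, 2.2, 4.8, 0.7)
  y <- c(2.0, 1.1, 4.9, 3.3, 4.1, 0.2)
  got <- spearman(x, y, exact = TRUE)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(spearman(1:9, rnorm(9), exact = TRUE), class = "invalid_input")
})

test_that("r-squared follows its defining sums", {
  m <- default_prediction_models()$F
  dms <- seq(10, 90, by = 10)
  expect_equal(r_squared(m, dms, predict_age(dms, m)), 1)

  # a model predicting (nearly) the grand mean explains (nearly) nothing
  ca <- c(4, 5, 6, 7, 8)
  flat <- prediction_model("M", 1 / mean(ca), 1e-12, 0.5)
  expect_equal(r_squared(flat, dms[1:5], ca), 0, tolerance = 1e-6)

  set.seed(45)
  ca2 <- predict_age(dms, m) + rnorm(9, 0, 0.5)
  expect_equal(r_squared(m, dms, ca2),
               1 - sum((ca2 - predict_age(dms, m))^2) /
                   sum((ca2 - mean(ca2))^2),
               tolerance = 1e-12)
  expect_error(r_squared(m, dms, rep(6, 9)), class = "degenerate_response")
})
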