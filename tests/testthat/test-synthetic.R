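test_that("default configuration reproduces the study's cohort structure", {
  cohort <- generate_cohort(generator_config(seed = 3), score_tab, conv_tab)
  expect_identical(nrow(cohort), 160L)
  expect_identical(sum(cohort$sex == "M"), 74L)
  expect_identical(sum(cohort$sex == "F"), 86L)
  expect_true(all(cohort$ca >= 3 & cohort$ca < 11))
  # every record's date-derived age lands in its generating cell
  counts <- as.data.frame(table(lower = floor(cohort$ca), sex = cohort$sex))
  ref <- reference_group_summary()
  merged <- merge(ref, counts,
                  by.x = c("lower", "sex"), by.y = c("lower", "sex"))
  expect_identical(nrow(merged), 16L)
  expect_identical(as.integer(merged$Freq), merged$n)
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generate_cohort(generator_config(seed = 8), score_tab, conv_tab)
  c2 <- generate_cohort(generator_config(seed = 8), score_tab, conv_tab)
  expect_identical(c1, c2)
  c3 <- generate_cohort(generator_config(seed = 9), score_tab, conv_tab)
  expect_false(identical(c1, c3))
})

test_that("stage quantisation is bounded and exact at the extremes", {
  for (sex in c("M", "F")) {
    top <- assign_stages_from_dms(100, score_tab, sex)
    expect_true(all(top == "H"))
    bottom <- assign_stages_from_dms(0, score_tab, sex)
    expect_true(all(bottom == "0"))
    bound <- quantisation_bound(score_tab, sex)
    realised <- vapply(seq(0, 100, by = 0.5), function(d) {
      stages <- assign_stages_from_dms(d, score_tab, sex)
      sum(score_lookup(score_tab, rep(sex, 7), fdi_teeth(), stages))
    }, numeric(1))
    err <- seq(0, 100, by = 0.5) - realised
    expect_true(all(abs(err) <= bound))
    # nearest-score quantisation is close to unbiased across the scale
    expect_lt(abs(mean(err)), 0.5)
  }
})

test_that("a noiseless, bias-free cohort round-trips age through staging", {
  ref <- reference_group_summary()
  cfg <- generator_config(
    biases = data.frame(lower = ref$lower, sex = ref$sex, bias = 0),
    age_noise_sd = 0, missing_left_rate = 0, seed = 10)
  cohort <- generate_cohort(cfg, score_tab, conv_tab)
  scored <- score_cohort(cohort, score_tab)$cohort
  est <- estimate_cohort(scored, conv_tab)
  # age error bounded by the quantisation bound mapped through the table,
  # evaluated empirically over the score grid (plus slack for the 2-dp CA)
  for (sex in c("M", "F")) {
    grid <- seq(0, 100, by = 0.25)
    ages <- dms_to_age(grid, sex, conv_tab)
    realised <- vapply(grid, function(d) {
      stages <- assign_stages_from_dms(d, score_tab, sex)
      sum(score_lookup(score_tab, rep(sex, 7), fdi_teeth(), stages))
    }, numeric(1))
    max_age_err <- max(abs(dms_to_age(realised, sex, conv_tab) - ages))
    sel <- est$sex == sex
    expect_true(all(abs(est$eda[sel] - est$ca[sel]) <= max_age_err + 0.02))
  }
})

test_that("missing-tooth events leave the contralateral readable", {
  cfg <- small_config()
  cfg$missing_left_rate <- 0.5
  cohort <- generate_cohort(cfg, score_tab, conv_tab)
  left <- as.matrix(cohort[tooth_cols("left")])
  right <- as.matrix(cohort[tooth_cols("right")])
  expect_true(any(is.na(left)))
  expect_true(all(!is.na(right[is.na(left)])))
  # scoring still succeeds for every record
  expect_identical(nrow(score_cohort(cohort, score_tab)$cohort), nrow(cohort))

  cfg$missing_both_rate <- 1
  gone <- generate_cohort(cfg, score_tab, conv_tab)
  out <- score_cohort(gone, score_tab)
  expect_identical(nrow(out$cohort), 0L)
  expect_identical(nrow(out$log), nrow(gone))
})

test_that("rating perturbation moves single stages at the configured rate", {
  stages <- rep("D", 5000)
  expect_identical(perturb_ratings(stages, 0, seed = 1), stages)

  all_flip <- perturb_ratings(stages, 1, seed = 2)
  expect_true(all(abs(stage_index(all_flip) - stage_index(stages)) == 1L))

  some <- perturb_ratings(stages, 0.1, seed = 3)
  frac <- mean(some != stages)
  se3 <- 3 * sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(frac - 0.1), se3)

  # clamping at the scale ends keeps codes valid
  ends <- perturb_ratings(rep(c("0", "H"), 50), 1, seed = 4)
  expect_true(all(ends %in% stage_codes()))
  expect_identical(perturb_ratings(NA_character_, 1, seed = 5), NA_character_)
})

test_that("model-pair simulation spans the requested ages deterministically", {
  m <- default_prediction_models()$M
  p1 <- simulate_model_pairs(74, m, seed = 6)
  p2 <- simulate_model_pairs(74, m, seed = 6)
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 74L)
  noiseless <- simulate_model_pairs(74, m, noise_sd = 0, seed = 7)
  expect_true(all(noiseless$ca >= 3 & noiseless$ca <= 10))
  expect_equal(predict_age(noiseless$dms, m), noiseless$ca, tolerance = 1e-9)
})
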