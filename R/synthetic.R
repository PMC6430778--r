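#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of the studied cohort so
#' every pipeline stage is testable without radiographs. Defaults reproduce
#' the study conditions: the published per-group sample sizes (74 males and
#' 86 females across eight yearly groups), the published per-group
#' estimation biases (mean EDA − CA in years), Gaussian age-scale noise of
#' 0.30 years on the latent dental age, occasional missing left teeth with
#' the contralateral available, and a 10% per-tooth rater flip rate for
#' retest simulation.
#'
#' @param group_sizes data frame with columns `lower`, `sex`, `n`
#'   (default: the published distribution, [reference_group_summary()])
#' @param biases data frame with columns `lower`, `sex`, `bias` in years
#'   (default: the published mean differences)
#' @param age_noise_sd SD (years) of Gaussian noise added to the latent
#'   dental age before inversion to a maturity score (default 0.30)
#' @param missing_left_rate per-tooth probability the left tooth is missing
#'   with the contralateral readable (default 0.05)
#' @param missing_both_rate per-tooth probability both sides are missing,
#'   making the record unscorable (default 0)
#' @param rater_flip_rate per-tooth probability a retest reading moves one
#'   stage (default 0.10)
#' @param seed integer root seed
#' @return a `generator_config` list
#' @export
generator_config <- function(group_sizes = NULL, biases = NULL,
                             age_noise_sd = 0.30,
                             missing_left_rate = 0.05,
                             missing_both_rate = 0,
                             rater_flip_rate = 0.10,
                             seed = 1L) {
  ref <- reference_group_summary()
  group_sizes <- group_sizes %||% ref[c("lower", "sex", "n")]
  biases <- biases %||%
    data.frame(lower = ref$lower, sex = ref$sex, bias = ref$mean_diff)
  stopifnot(all(group_sizes$n >= 0), age_noise_sd >= 0,
            missing_left_rate >= 0, missing_left_rate <= 1,
            missing_both_rate >= 0, missing_both_rate <= 1,
            rater_flip_rate >= 0, rater_flip_rate <= 1)
  structure(list(group_sizes = group_sizes, biases = biases,
                 age_noise_sd = age_noise_sd,
                 missing_left_rate = missing_left_rate,
                 missing_both_rate = missing_both_rate,
                 rater_flip_rate = rater_flip_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' For each (sex, age group) cell, chronological age is drawn uniformly
#' within the yearly interval (inset 0.01 years from each bound so that
#' date-derived ages stay in the generating group); the latent dental age is
#' the chronological age plus the configured group bias plus Gaussian noise;
#' the latent maturity score is the conversion-table inverse of that dental
#' age (clamped to the table range); per-tooth stages quantise the latent
#' score ([assign_stages_from_dms()]); and birth/radiograph dates are laid
#' out on a first-of-month grid so the day-count age reproduces the drawn
#' age to two decimals. Missing-tooth events move the reading to the
#' contralateral column (or blank both sides at `missing_both_rate`).
#'
#' Identical seeds give identical cohorts.
#'
#' @param config a [generator_config()]
#' @param score_table a [score_table][load_score_table] (default: packaged)
#' @param conversion_table a
#'   [conversion_table][load_conversion_table] (default: packaged)
#' @return cohort data frame with identifying columns, stage columns and the
#'   generating values `ca` (date-derived, 2 dp), `latent_age`, `latent_dms`
#' @export
generate_cohort <- function(config = generator_config(),
                            score_table = load_score_table(),
                            conversion_table = load_conversion_table()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    rows <- list()
    id <- 0L
    for (i in seq_len(nrow(config$group_sizes))) {
      lower <- config$group_sizes$lower[i]
      sex <- config$group_sizes$sex[i]
      n <- config$group_sizes$n[i]
      if (n == 0) next
      bias <- config$biases$bias[config$biases$lower == lower &
                                 config$biases$sex == sex]
      if (length(bias) != 1) {
        stop_dentalage(sprintf("no bias configured for cell (%s, %d)", sex, lower),
                       "invalid_config")
      }
      ca <- stats::runif(n, lower + 0.01, lower + 1 - 0.01)
      target <- ca + bias + stats::rnorm(n, 0, config$age_noise_sd)
      k <- conversion_table$knots[[sex]]
      target <- pmin(pmax(target, k$age[1]), k$age[nrow(k)])
      dms <- age_to_dms(target, sex, conversion_table)
      for (j in seq_len(n)) {
        id <- id + 1L
        days <- round(ca[j] * 365.25)
        dob0 <- as.Date("2017-06-15") - days
        dob <- as.Date(format(dob0, "%Y-%m-01"))
        dor <- dob + days
        stages <- assign_stages_from_dms(dms[j], score_table, sex)
        left <- stages
        right <- stats::setNames(rep(NA_character_, 7), tooth_cols("right"))
        u <- stats::runif(7)
        gone_both <- u < config$missing_both_rate
        gone_left <- !gone_both &
          u < config$missing_both_rate + config$missing_left_rate
        right[gone_left] <- stages[gone_left]
        left[gone_left | gone_both] <- NA_character_
        rows[[id]] <- data.frame(
          child_id = sprintf("S%04d", id), sex = sex,
          dob = dob, dor = dor,
          as.list(stats::setNames(left, tooth_cols("left"))),
          as.list(right),
          ca = compute_chronological_age(dob, dor),
          latent_age = target[j], latent_dms = dms[j])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Quantise a maturity score into per-tooth stages
#'
#' Deterministic inverse of [compute_dms()] up to stage quantisation: each
#' tooth gets the stage whose score is nearest to the tooth's proportional
#' share `(dms/100) * score(tooth, H)` (ties resolved to the earlier stage).
#' The nearest-score rule is unbiased: re-scoring the assigned stages gives
#' a realised score within half the sum of the per-tooth maximum single-stage
#' increments of the latent score, with mean error near zero across scores —
#' so cohort-level biases survive the stage round-trip.
#'
#' @param dms latent maturity score in `[0, 100]`
#' @param table a [score_table][load_score_table]
#' @param sex `"M"` or `"F"`
#' @return named character vector of stage codes (`t31`..`t37`)
#' @export
assign_stages_from_dms <- function(dms, table, sex) {
  stopifnot(dms >= 0, dms <= 100)
  stages <- vapply(as.character(fdi_teeth()), function(to) {
    sc <- table$scores[check_sex(sex), to, ]
    target <- dms / 100 * sc[["H"]]
    stage_codes()[which.min(abs(sc - target))]
  }, character(1))
  stats::setNames(stages, tooth_cols("left"))
}

#' Worst-case stage-quantisation error of a score table
#'
#' Half the sum over teeth of the largest single-stage score increment: the
#' bound on `|dms - realised dms|` under the nearest-score rule of
#' [assign_stages_from_dms()].
#'
#' @param table a [score_table][load_score_table]
#' @param sex `"M"` or `"F"`
#' @return numeric bound in maturity-score points
#' @export
quantisation_bound <- function(table, sex) {
  sum(apply(table$scores[check_sex(sex), , ], 1, function(s) max(diff(s)))) / 2
}

#' Perturb stage ratings to simulate a second reading
#'
#' Each rating independently moves one stage up or down (equal probability)
#' with probability `rate`, clamped at the scale ends; `NA` (absent tooth)
#' stays `NA`.
#'
#' @param stages character vector (or matrix) of stage codes, `NA` allowed
#' @param rate per-rating flip probability in `[0, 1]`
#' @param seed optional integer seed
#' @return perturbed stages, same shape as the input
#' @export
perturb_ratings <- function(stages, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  go <- function() {
    idx <- stage_index(stages)
    flip <- !is.na(idx) & stats::runif(length(idx)) < rate
    step <- ifelse(stats::runif(length(idx)) < 0.5, -1L, 1L)
    idx[flip] <- pmin(pmax(idx[flip] + step[flip], 0L), 8L)
    out <- stage_codes()[idx + 1L]
    attributes(out) <- attributes(stages)
    out
  }
  if (is.null(seed)) go() else withr::with_seed(seed, go())
}

#' Perturb every stage column of a cohort
#'
#' Applies [perturb_ratings()] jointly to all left and right stage columns,
#' producing a simulated retest scoring of the same radiographs.
#'
#' @param cohort cohort data frame
#' @param rate per-rating flip probability
#' @param seed optional integer seed
#' @return cohort with perturbed stage columns
#' @export
perturb_cohort_ratings <- function(cohort, rate, seed = NULL) {
  cols <- intersect(c(tooth_cols("left"), tooth_cols("right")), names(cohort))
  m <- as.matrix(cohort[cols])
  m2 <- perturb_ratings(m, rate, seed = seed)
  cohort[cols] <- as.data.frame(m2, stringsAsFactors = FALSE)
  cohort
}

#' Simulate (maturity score, age) pairs from a prediction model
#'
#' Draws latent ages uniformly over `age_range`, inverts the model to get
#' noiseless maturity scores, and adds Gaussian noise to the age — the
#' standard setup for checking that calibration recovers a known model.
#'
#' @param n number of pairs
#' @param model a [prediction_model()]
#' @param age_range ages (years) spanned by the latent draw (default 3-10)
#' @param noise_sd Gaussian SD (years) added to the age (default 0.3)
#' @param seed optional integer seed
#' @return data frame with columns `dms`, `ca`
#' @export
simulate_model_pairs <- function(n, model, age_range = c(3, 10),
                                 noise_sd = 0.3, seed = NULL) {
  go <- function() {
    u <- stats::runif(n, age_range[1], age_range[2])
    data.frame(dms = invert_prediction(u, model),
               ca = u + stats::rnorm(n, 0, noise_sd))
  }
  if (is.null(seed)) go() else withr::with_seed(seed, go())
}
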