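#' Estimate dental ages for a scored cohort
#'
#' Adds `eda` (estimated dental age via the conversion table) to a cohort
#' that already carries `dms` and `sex`.
#'
#' @param cohort data frame with `sex` and `dms` columns
#' @param conversion_table a [conversion_table][load_conversion_table]
#' @param policy out-of-table policy passed to [dms_to_age()]
#' @return the cohort with an `eda` column
#' @export
estimate_cohort <- function(cohort, conversion_table = load_conversion_table(),
                            policy = "error") {
  cohort$eda <- rep(NA_real_, nrow(cohort))
  for (sx in unique(cohort$sex)) {
    sel <- cohort$sex == sx
    cohort$eda[sel] <- dms_to_age(cohort$dms[sel], sx, conversion_table,
                                  policy = policy)
  }
  cohort
}

#' Run the full study reproduction
#'
#' Executes the study pipeline in order on a synthetic (or supplied) cohort:
#' score the seven teeth (contralateral substitution, unscorable records
#' logged out) -> convert maturity scores to estimated dental ages ->
#' exclude estimates below 2.5 years -> stratify by age group and sex and
#' compare EDA with CA -> regress bias on age per sex -> calibrate the
#' logistic growth prediction model per sex -> test-retest reliability on a
#' 20% subsample with simulated second readings.
#'
#' All randomness flows from `config$seed`: the cohort uses the seed itself,
#' retest selection `seed + 1`, rater noise `seed + 2`. Two runs with the
#' same configuration give identical reports.
#'
#' @param config a [generator_config()]
#' @param score_table a [score_table][load_score_table]
#' @param conversion_table a [conversion_table][load_conversion_table]
#' @param cohort optional pre-built cohort (bypasses generation)
#' @param min_eda exclusion threshold in years (default 2.5)
#' @param retest_fraction subsample fraction re-scored (default 0.20)
#' @return a `study_report` list: `cohort_summary`, `accuracy` (stratified
#'   table), `totals` (per-sex comparison), `bias_fit` (per sex),
#'   `calibration` (per sex), `reliability`, `exclusions`, `provenance`
#' @export
run_study <- function(config = generator_config(),
                      score_table = load_score_table(),
                      conversion_table = load_conversion_table(),
                      cohort = NULL, min_eda = 2.5, retest_fraction = 0.20) {
  cohort <- cohort %||% generate_cohort(config, score_table, conversion_table)
  n_input <- nrow(cohort)
  if (!"ca" %in% names(cohort)) {
    cohort$ca <- compute_chronological_age(cohort$dob, cohort$dor)
  }

  scored <- score_cohort(cohort, score_table)
  est <- estimate_cohort(scored$cohort, conversion_table, policy = "clamp")
  filt <- exclude_below_min_age(est, min_eda = min_eda)
  kept <- filt$retained
  exclusions <- rbind(scored$log, filt$log)

  if (!nrow(kept)) {
    return(structure(list(cohort_summary = NULL, accuracy = NULL,
                          totals = NULL, bias_fit = NULL, calibration = NULL,
                          reliability = NULL, exclusions = exclusions,
                          provenance = list(seed = config$seed,
                                            n_input = n_input, n_retained = 0L)),
                     class = "study_report"))
  }

  kept$group <- assign_age_group(kept$ca)
  cohort_summary <- as.data.frame(table(group = kept$group, sex = kept$sex),
                                  responseName = "n")

  acc <- accuracy_table(kept)
  totals <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    sub <- kept[kept$sex == sx, ]
    cbind(data.frame(sex = sx), as.data.frame(compare_group(sub$ca, sub$eda)))
  }))

  bias_fit <- lapply(stats::setNames(c("M", "F"), c("M", "F")), function(sx) {
    sub <- kept[kept$sex == sx, ]
    bias_regression(sub$ca, sub$eda - sub$ca)
  })

  calibration <- lapply(stats::setNames(c("M", "F"), c("M", "F")), function(sx) {
    sub <- kept[kept$sex == sx, ]
    dms <- sub$dms
    attr(dms, "sex") <- sx
    fit_logistic_growth(dms, sub$ca, asymptote = "free")
  })

  sub <- select_retest_subsample(kept, fraction = retest_fraction,
                                 seed = config$seed + 1L)
  retest <- perturb_cohort_ratings(sub, config$rater_flip_rate,
                                   seed = config$seed + 2L)
  reliability <- reliability_report(sub, retest, score_table)

  structure(list(cohort_summary = cohort_summary, accuracy = acc,
                 totals = totals, bias_fit = bias_fit,
                 calibration = calibration, reliability = reliability,
                 exclusions = exclusions,
                 provenance = list(seed = config$seed, n_input = n_input,
                                   n_scored = nrow(scored$cohort),
                                   n_retained = nrow(kept),
                                   retest_n = nrow(sub))),
            class = "study_report")
}

#' Serialise a study report to JSON
#'
#' Stable key order and unboxed scalars, so identical runs produce
#' byte-identical files.
#'
#' @param report a `study_report` from [run_study()]
#' @param path output path; `NULL` returns the JSON string
#' @return the JSON string, invisibly when written to a file
#' @export
write_report <- function(report, path = NULL) {
  ser <- report
  ser$calibration <- lapply(ser$calibration, function(cr) {
    list(sex = cr$model$sex, a = cr$model$a, b = cr$model$b, c = cr$model$c,
         r_squared = cr$r_squared, spearman_rho = cr$spearman_rho,
         fit_method = cr$fit_method, n = cr$n, converged = cr$converged)
  })
  class(ser) <- NULL
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study report (seed %d): %d records in, %d retained\n",
              x$provenance$seed, x$provenance$n_input, x$provenance$n_retained))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  %d stratified accuracy rows; overall bias M %.3f / F %.3f yr\n",
                nrow(x$accuracy),
                x$bias_fit$M$overall_mean_diff, x$bias_fit$F$overall_mean_diff))
    cat(sprintf("  retest agreement %.2f%% (kappa %.3f)\n",
                x$reliability$percent_agreement, x$reliability$kappa))
  }
  invisible(x)
}
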