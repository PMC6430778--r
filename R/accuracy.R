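#' Two-sample t comparison from summary statistics
#'
#' Pooled-variance (Student) independent-samples t-test computed from group
#' summaries alone — the form needed to reproduce published tables where raw
#' data are unavailable. Sample 1 is chronological age, sample 2 the
#' estimated dental age, so `mean_diff = mean2 - mean1` is the estimation
#' bias. Welch's unequal-variance form is available via `var_equal = FALSE`.
#'
#' Degenerate variances are handled explicitly: if both SDs are zero the
#' statistic is undefined; equal means return `(0, 0, 1)` by convention and
#' unequal means are flagged (`degenerate = TRUE`, `p = 0`).
#'
#' @param mean1,sd1,n1 summary of sample 1 (sd uses the n-1 denominator)
#' @param mean2,sd2,n2 summary of sample 2
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise
#' @return list: `mean_diff`, `t_stat`, `df`, `p_value`, `category`
#'   (see [classify_p()]), `degenerate`
#' @examples
#' compare_from_summary(7.28, 0.32, 10, 7.86, 0.27, 10)
#' @export
compare_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) {
    stop_dentalage("both samples need n >= 2 for a t-test", "insufficient_data")
  }
  if (sd1 < 0 || sd2 < 0) {
    stop_dentalage("standard deviations must be non-negative", "invalid_summary")
  }
  md <- mean2 - mean1
  if (sd1 == 0 && sd2 == 0) {
    if (md == 0) {
      return(list(mean_diff = 0, t_stat = 0, df = n1 + n2 - 2, p_value = 1,
                  category = classify_p(1), degenerate = TRUE))
    }
    return(list(mean_diff = md, t_stat = Inf * sign(md), df = n1 + n2 - 2,
                p_value = 0, category = classify_p(0), degenerate = TRUE))
  }
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1/n1 + 1/n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2/(n1 - 1) + v2^2/(n2 - 1))
  }
  t_stat <- md / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(mean_diff = md, t_stat = t_stat, df = df, p_value = p,
       category = classify_p(p), degenerate = FALSE)
}

#' Compare estimated dental age with chronological age in one stratum
#'
#' Means, sample SDs and the independent-samples t-test for one age-sex
#' group, mirroring one row of a stratified validation table. With a single
#' observation in either sample the row is reported descriptively with the
#' test omitted (`NA`).
#'
#' @param ca_values chronological ages (years)
#' @param eda_values estimated dental ages (years)
#' @param var_equal pooled variance if `TRUE` (default)
#' @return list: `n`, `ca_mean`, `ca_sd`, `eda_mean`, `eda_sd`, `mean_diff`,
#'   `t_stat`, `p_value`, `category`
#' @export
compare_group <- function(ca_values, eda_values, var_equal = TRUE) {
  if (!length(ca_values) || !length(eda_values)) {
    stop_dentalage("empty sample", "insufficient_data")
  }
  out <- list(n = length(eda_values),
              ca_mean = mean(ca_values), ca_sd = stats::sd(ca_values),
              eda_mean = mean(eda_values), eda_sd = stats::sd(eda_values),
              mean_diff = mean(eda_values) - mean(ca_values),
              t_stat = NA_real_, p_value = NA_real_, category = NA_character_)
  if (length(ca_values) >= 2 && length(eda_values) >= 2) {
    ts <- compare_from_summary(out$ca_mean, out$ca_sd, length(ca_values),
                               out$eda_mean, out$eda_sd, length(eda_values),
                               var_equal = var_equal)
    out$t_stat <- ts$t_stat
    out$p_value <- ts$p_value
    out$category <- ts$category
  }
  out
}

#' Significance category of a p-value
#'
#' The reporting convention of the study: non-significant if p >= 0.05
#' (boundary inclusive), significant if p < 0.05, highly significant if
#' p < 0.01, very highly significant if p < 0.001; the most extreme
#' applicable label is returned. Monotone: a smaller p never gets a weaker
#' label.
#'
#' @param p numeric p-value(s) in `[0, 1]`
#' @return character vector of category labels
#' @examples
#' classify_p(c(0.05, 0.02, 0.005, 0.0005))
#' @export
classify_p <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop_dentalage("p-values must lie in [0, 1]", "invalid_p")
  }
  ifelse(p < 0.001, "very highly significant",
  ifelse(p < 0.01, "highly significant",
  ifelse(p < 0.05, "significant", "non-significant")))
}

#' Regression of estimation bias on chronological age
#'
#' Ordinary least squares of the per-child differences EDA − CA on CA — the
#' scatter-plot-with-regression-line summary of whether bias drifts with
#' age — plus the overall mean and sample SD of the differences.
#'
#' @param ca_values chronological ages (years)
#' @param diffs per-child EDA − CA differences (years), same length
#' @return list: `slope` (years per year), `intercept` (years),
#'   `overall_mean_diff`, `overall_sd`, `n`
#' @export
bias_regression <- function(ca_values, diffs) {
  if (length(ca_values) != length(diffs) || length(diffs) < 2) {
    stop_dentalage("need equal-length arrays with at least 2 points",
                   "insufficient_data")
  }
  if (stats::var(ca_values) == 0) {
    stop_dentalage("all chronological ages identical: slope undefined",
                   "undefined_slope")
  }
  fit <- stats::lm(diffs ~ ca_values)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       overall_mean_diff = mean(diffs),
       overall_sd = stats::sd(diffs),
       n = length(diffs))
}

#' Stratified accuracy table for a cohort
#'
#' Builds the full validation table: one [compare_group()] row per age group
#' and sex, in the study's layout, from a cohort carrying `ca`, `eda` and
#' `sex` columns.
#'
#' @param cohort data frame with columns `sex`, `ca`, `eda`
#' @param var_equal pooled variance if `TRUE` (default)
#' @return data frame with columns `group`, `sex`, `n`, `ca_mean`, `ca_sd`,
#'   `eda_mean`, `eda_sd`, `mean_diff`, `t_stat`, `p_value`, `category`
#' @export
accuracy_table <- function(cohort, var_equal = TRUE) {
  cohort$group <- assign_age_group(cohort$ca)
  cells <- expand.grid(group = levels(cohort$group), sex = c("M", "F"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- cohort[cohort$group == cells$group[i] & cohort$sex == cells$sex[i], ]
    if (!nrow(sub)) return(NULL)
    cg <- compare_group(sub$ca, sub$eda, var_equal = var_equal)
    cbind(data.frame(group = cells$group[i], sex = cells$sex[i]),
          as.data.frame(cg))
  })
  out <- do.call(rbind, rows)
  out[order(match(out$group, age_groups()$label), out$sex), , drop = FALSE]
}
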