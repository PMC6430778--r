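#' Published group-level summary statistics for the studied cohort
#'
#' The stratified results of the source study of 160 Egyptian children (74
#' males, 86 females, ages 3 to <11 in yearly groups): per age group and sex,
#' the group size, mean and SD of chronological age (CA) and of the estimated
#' dental age (EDA) obtained with the standard seven-tooth conversion, the
#' printed mean difference EDA − CA, and the printed p-value of the
#' independent-samples t-test. These printed summaries are inputs: they seed
#' the synthetic-cohort generator's default bias pattern and serve as a
#' fixture for summary-statistic arithmetic.
#'
#' `eda_dp` records the number of decimals the EDA mean was printed with
#' (four male rows were printed at one decimal, limiting arithmetic checks
#' on those rows).
#'
#' @return data frame with columns `lower` (group lower bound, years), `sex`,
#'   `n`, `ca_mean`, `ca_sd`, `eda_mean`, `eda_sd`, `mean_diff`, `p_printed`,
#'   `eda_dp`
#' @export
reference_group_summary <- function() {
  g <- 3:10
  male <- data.frame(
    lower = g, sex = "M",
    n = c(10L, 10L, 11L, 5L, 10L, 10L, 8L, 10L),
    ca_mean = c(3.21, 4.39, 5.08, 6.00, 7.28, 8.35, 9.00, 10.21),
    ca_sd = c(0.35, 0.39, 0.27, 0.00, 0.32, 0.28, 0.00, 0.25),
    eda_mean = c(4.40, 4.64, 5.99, 6.10, 7.86, 8.60, 8.40, 10.70),
    eda_sd = c(1.04, 0.81, 0.66, 1.10, 0.27, 0.38, 0.39, 0.35),
    mean_diff = c(1.19, 0.25, 0.90, 0.18, 0.58, 0.25, -0.60, 0.57),
    p_printed = c("0.006", "0.393", "0.001", "0.725", "<0.001", "0.116",
                  "0.003", "0.001"),
    eda_dp = c(2L, 2L, 2L, 1L, 2L, 1L, 1L, 1L))
  female <- data.frame(
    lower = g, sex = "F",
    n = c(8L, 9L, 15L, 10L, 10L, 10L, 12L, 12L),
    ca_mean = c(3.67, 4.08, 5.32, 6.42, 7.34, 8.28, 9.20, 10.42),
    ca_sd = c(0.30, 0.16, 0.29, 0.27, 0.31, 0.33, 0.23, 0.32),
    eda_mean = c(4.55, 4.68, 5.92, 6.86, 7.57, 8.36, 9.14, 10.41),
    eda_sd = c(0.79, 0.78, 0.83, 0.45, 0.30, 0.52, 0.47, 0.50),
    mean_diff = c(0.87, 0.60, 0.60, 0.44, 0.23, 0.08, -0.06, -0.008),
    p_printed = c("0.017", "0.052", "0.018", "0.018", "0.118", "0.691",
                  "0.671", "0.962"),
    eda_dp = 2L)
  rbind(male, female)
}

#' Published whole-sample bias summaries
#'
#' Overall EDA − CA mean (SD) per sex as printed with the study's
#' bias-versus-age scatter analysis.
#'
#' @return data frame with columns `sex`, `mean_diff`, `sd_diff`
#' @export
reference_overall_bias <- function() {
  data.frame(sex = c("M", "F"),
             mean_diff = c(0.4662, 0.3256),
             sd_diff = c(0.78675, 0.6920))
}
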