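#' Random subsample for test-retest scoring
#'
#' Simple random sample without replacement of `round_half_up(fraction * n)`
#' records, reproducible under a fixed seed — the design used to re-score a
#' fifth of the radiographs two weeks later.
#'
#' @param cohort cohort data frame
#' @param fraction sampling fraction in `[0, 1]` (default 0.20)
#' @param seed integer seed (optional; current RNG state used when `NULL`)
#' @return the sampled rows of `cohort`
#' @export
select_retest_subsample <- function(cohort, fraction = 0.20, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(cohort)
  k <- round_half_up(fraction * n)
  pick <- function() sort(sample.int(n, k))
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  cohort[idx, , drop = FALSE]
}

#' Percent agreement between two stage ratings
#'
#' Exact-match agreement plus the direction of one-stage disagreements:
#' `n_ahead` counts items the second rating places one stage later than the
#' first, `n_behind` one stage earlier.
#'
#' @param ratings1,ratings2 equal-length vectors of stage codes
#' @return list: `percent` (0-100), `n_ahead`, `n_behind`, `n_items`
#' @examples
#' percent_agreement(c("C", "D", "E", "F"), c("D", "D", "E", "E"))
#' @export
percent_agreement <- function(ratings1, ratings2) {
  if (length(ratings1) != length(ratings2) || !length(ratings1)) {
    stop_dentalage("ratings must be equal-length and non-empty", "invalid_input")
  }
  d <- stage_index(ratings2) - stage_index(ratings1)
  list(percent = 100 * mean(d == 0),
       n_ahead = sum(d == 1),
       n_behind = sum(d == -1),
       n_items = length(d))
}

#' Cohen's kappa for two ratings
#'
#' Unweighted chance-corrected agreement,
#' `kappa = (p_o - p_e)/(1 - p_e)`, with expected agreement `p_e` from the
#' product of marginal proportions. The p-value tests `kappa = 0` with the
#' large-sample normal approximation (Fleiss' standard error under the null).
#' When both raters are constant and identical, agreement is perfect but
#' chance-uncorrectable (`p_e = 1`): kappa is reported as 1 with
#' `degenerate = TRUE`.
#'
#' @param ratings1,ratings2 equal-length vectors (length >= 2) of category
#'   labels
#' @return list: `kappa`, `p_value`, `p_o`, `p_e`, `n`, `degenerate`
#' @export
cohens_kappa <- function(ratings1, ratings2) {
  n <- length(ratings1)
  if (length(ratings2) != n || n < 2) {
    stop_dentalage("need two equal-length rating vectors of at least 2",
                   "invalid_input")
  }
  lev <- sort(unique(c(ratings1, ratings2)))
  f1 <- factor(ratings1, levels = lev)
  f2 <- factor(ratings2, levels = lev)
  tab <- table(f1, f2) / n
  p_o <- sum(diag(tab))
  pr <- rowSums(tab)
  pc <- colSums(tab)
  p_e <- sum(pr * pc)
  if (1 - p_e < 1e-12) {
    return(list(kappa = 1, p_value = NA_real_, p_o = p_o, p_e = p_e, n = n,
                degenerate = TRUE))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se0 <- sqrt(p_e + p_e^2 - sum(pr * pc * (pr + pc))) / ((1 - p_e) * sqrt(n))
  z <- kappa / se0
  list(kappa = kappa, p_value = 2 * stats::pnorm(-abs(z)),
       p_o = p_o, p_e = p_e, n = n, degenerate = FALSE)
}

#' Pearson test-retest correlation
#'
#' Linear correlation between maturity scores (or any paired continuous
#' rating) at test and retest, with the usual two-sided t-test.
#'
#' @param x,y equal-length numeric vectors (length >= 3), each with nonzero
#'   variance
#' @return list: `r`, `p_value`, `n`
#' @export
pearson_testretest <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    stop_dentalage("need two equal-length vectors of at least 3 values",
                   "invalid_input")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_dentalage("zero variance: correlation undefined",
                   "undefined_correlation")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Full reliability report for a test-retest pair of cohorts
#'
#' Pools the resolved stages of all seven teeth across the subsample for
#' percent agreement and Cohen's kappa (with a per-tooth breakdown), and
#' correlates test and retest maturity scores.
#'
#' @param test,retest cohorts of identical records save for stage codes
#' @param table a [score_table][load_score_table]
#' @return list: `n_items`, `percent_agreement`, `n_ahead`, `n_behind`,
#'   `kappa`, `kappa_p`, `pearson_r`, `pearson_p`, `per_tooth` (data frame)
#' @export
reliability_report <- function(test, retest, table) {
  stopifnot(nrow(test) == nrow(retest))
  get_stages <- function(cohort, tooth) {
    vapply(seq_len(nrow(cohort)),
           function(i) resolve_stage(cohort[i, ], tooth), character(1))
  }
  s1 <- lapply(fdi_teeth(), get_stages, cohort = test)
  s2 <- lapply(fdi_teeth(), get_stages, cohort = retest)
  pooled1 <- unlist(s1)
  pooled2 <- unlist(s2)
  pa <- percent_agreement(pooled1, pooled2)
  kp <- cohens_kappa(pooled1, pooled2)
  dms1 <- vapply(seq_len(nrow(test)),
                 function(i) compute_dms(test[i, ], table), numeric(1))
  dms2 <- vapply(seq_len(nrow(retest)),
                 function(i) compute_dms(retest[i, ], table), numeric(1))
  pr <- pearson_testretest(dms1, dms2)
  per_tooth <- do.call(rbind, lapply(seq_along(s1), function(k) {
    pak <- percent_agreement(s1[[k]], s2[[k]])
    data.frame(tooth = fdi_teeth()[k], percent = pak$percent,
               n_ahead = pak$n_ahead, n_behind = pak$n_behind)
  }))
  list(n_items = pa$n_items, percent_agreement = pa$percent,
       n_ahead = pa$n_ahead, n_behind = pa$n_behind,
       kappa = kp$kappa, kappa_p = kp$p_value,
       pearson_r = pr$r, pearson_p = pr$p_value,
       per_tooth = per_tooth)
}
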