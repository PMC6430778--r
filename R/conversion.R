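#' Load a maturity-score-to-age conversion table
#'
#' A conversion table maps the dental maturity score to the 50th-percentile
#' dental age, per sex, as an ordered sequence of knots. Knots must be
#' strictly increasing in score and strictly increasing in age, with at least
#' two knots per sex and a minimum age knot below 2.5 years (the estimation
#' range extends below the study's inclusion threshold). Estimation between
#' knots is piecewise linear ([dms_to_age()]).
#'
#' The packaged table
#' (`system.file("extdata", "conversion_table_synthetic.csv", package = "dentalage")`)
#' is a synthetic stand-in for the published percentile tables: a smooth
#' monotone curve spanning ages ~1.9 to ~12 over scores 0-100.
#'
#' @param path CSV with columns `sex`, `dms`, `age`; default is the packaged
#'   synthetic table
#' @return a `conversion_table` object (list of per-sex knot data frames)
#' @export
load_conversion_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "conversion_table_synthetic.csv",
                                package = "dentalage")
  df <- utils::read.csv(path)
  as_conversion_table(df)
}

#' @param df data frame with columns `sex`, `dms`, `age`
#' @rdname load_conversion_table
#' @export
as_conversion_table <- function(df) {
  if (!all(c("sex", "dms", "age") %in% names(df))) {
    stop_dentalage("conversion table needs columns sex, dms, age",
                   "invalid_conversion_table")
  }
  check_sex(df$sex)
  if (!all(c("M", "F") %in% df$sex)) {
    stop_dentalage("conversion table must cover both sexes",
                   "invalid_conversion_table")
  }
  knots <- lapply(split(df[c("dms", "age")], df$sex), function(k) {
    k <- k[order(k$dms), , drop = FALSE]
    if (nrow(k) < 2) {
      stop_dentalage("conversion table: fewer than 2 knots for a sex",
                     "invalid_conversion_table")
    }
    if (any(diff(k$dms) <= 0) || any(diff(k$age) < 0)) {
      stop_dentalage(
        "conversion table: knots must strictly increase in dms and not decrease in age",
        "invalid_conversion_table")
    }
    if (min(k$age) >= 2.5) {
      stop_dentalage("conversion table: minimum age knot must be below 2.5 years",
                     "invalid_conversion_table")
    }
    rownames(k) <- NULL
    k
  })
  structure(list(knots = knots), class = "conversion_table")
}

#' Convert maturity scores to estimated dental ages
#'
#' Piecewise-linear interpolation between the conversion-table knots; exact
#' at knots. Scores outside the knot range raise an out-of-table error by
#' default; `policy = "clamp"` returns the boundary age instead.
#'
#' @param dms numeric maturity score(s)
#' @param sex `"M"` or `"F"` (scalar)
#' @param table a [conversion_table][load_conversion_table]
#' @param policy `"error"` (default) or `"clamp"` for scores outside the table
#' @return estimated dental age(s) in decimal years
#' @export
dms_to_age <- function(dms, sex, table, policy = c("error", "clamp")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "conversion_table"), length(sex) == 1)
  k <- table$knots[[check_sex(sex)]]
  out_of <- dms < k$dms[1] | dms > k$dms[nrow(k)]
  if (any(out_of) && policy == "error") {
    stop_dentalage(sprintf(
      "maturity score %s outside conversion table range [%g, %g]",
      paste(signif(dms[out_of], 6), collapse = ", "),
      k$dms[1], k$dms[nrow(k)]), "out_of_table")
  }
  stats::approx(k$dms, k$age, xout = dms, rule = 2)$y
}

#' Invert a conversion table: age to maturity score
#'
#' Piecewise-linear inverse of [dms_to_age()]; used by the synthetic-cohort
#' generator to find the latent maturity score whose table conversion equals
#' a target dental age.
#'
#' @inheritParams dms_to_age
#' @param age target age(s) in decimal years, within the table's age range
#' @return maturity score(s)
#' @export
age_to_dms <- function(age, sex, table, policy = c("error", "clamp")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "conversion_table"), length(sex) == 1)
  k <- table$knots[[check_sex(sex)]]
  out_of <- age < k$age[1] | age > k$age[nrow(k)]
  if (any(out_of) && policy == "error") {
    stop_dentalage(sprintf("age %s outside conversion table range [%g, %g]",
                           paste(signif(age[out_of], 6), collapse = ", "),
                           k$age[1], k$age[nrow(k)]), "out_of_table")
  }
  stats::approx(k$age, k$dms, xout = age, rule = 2, ties = "ordered")$y
}

#' Logistic growth prediction model
#'
#' The population-specific prediction equation `CA = 1/(a + b * c^DMS)`:
#' a bounded, strictly increasing growth curve in the maturity score with
#' lower asymptote `1/(a + b)` and upper asymptote `1/a` years. `a` is the
#' inverse of the upper age asymptote (1/years), `b` a scale (1/years), and
#' `c` the dimensionless exponential decay base, `0 < c < 1`.
#'
#' @param sex `"M"` or `"F"`
#' @param a,b,c model coefficients
#' @return a `prediction_model` object
#' @examples
#' m <- prediction_model("M", 0.083, 0.351, 0.969)
#' predict_age(c(0, 50, 100), m)
#' @export
prediction_model <- function(sex, a, b, c) {
  check_sex(sex)
  if (!(a > 0 && b > 0 && c > 0 && c < 1)) {
    stop_dentalage("prediction model needs a > 0, b > 0 and 0 < c < 1",
                   "invalid_model")
  }
  structure(list(sex = sex, a = a, b = b, c = c), class = "prediction_model")
}

#' Reference prediction models fitted for the studied population
#'
#' The published coefficients, stored at their printed 3-decimal precision:
#' males `CA = 1/(0.083 + 0.351 x 0.969^DMS)`, females
#' `CA = 1/(0.083 + 0.350 x 0.970^DMS)`.
#'
#' @return named list of [prediction_model()]s, elements `M` and `F`
#' @export
default_prediction_models <- function() {
  list(M = prediction_model("M", 0.083, 0.351, 0.969),
       F = prediction_model("F", 0.083, 0.350, 0.970))
}

#' Predict age from a maturity score
#'
#' Evaluates `1/(a + b * c^dms)`. Defined for any real `dms`; values outside
#' `[0, 100]` are permitted mathematically (the curve stays between its
#' asymptotes) but are flagged with a warning since they are not realisable
#' maturity scores.
#'
#' @param dms numeric maturity score(s)
#' @param model a [prediction_model()]
#' @return predicted age(s) in decimal years
#' @export
predict_age <- function(dms, model) {
  stopifnot(inherits(model, "prediction_model"))
  if (any(dms < 0 | dms > 100)) {
    warning("maturity score outside [0, 100]; extrapolating the growth curve")
  }
  1 / (model$a + model$b * model$c^dms)
}

#' Invert the prediction equation
#'
#' Algebraic inverse `dms = ln((1/age - a)/b) / ln(c)`, defined for
#' `0 < age < 1/a` (the upper asymptote). Ages below `1/(a + b)` — the
#' prediction at a maturity score of zero — invert to negative scores, which
#' are mathematically valid but not realisable stagings.
#'
#' @param age age(s) in decimal years, strictly below the upper asymptote
#' @param model a [prediction_model()]
#' @return maturity score(s); round-trips through [predict_age()] to within
#'   1e-9
#' @export
invert_prediction <- function(age, model) {
  stopifnot(inherits(model, "prediction_model"))
  hi <- 1 / model$a
  if (any(age <= 0 | age >= hi)) {
    stop_dentalage(sprintf(
      "age not invertible: the model's upper asymptote bounds ages below %.4f",
      hi), "non_invertible")
  }
  log((1 / age - model$a) / model$b) / log(model$c)
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("prediction model (%s): CA = 1/(%.3f + %.3f x %.3f^DMS)\n",
              x$sex, x$a, x$b, x$c))
  cat(sprintf("  age range (%.3f, %.3f) years\n", 1/(x$a + x$b), 1/x$a))
  invisible(x)
}
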