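#' Fit the logistic growth prediction model
#'
#' Fits `CA = 1/(a + b * c^DMS)` to (maturity score, chronological age)
#' pairs. "Logistic" here is growth-curve estimation (a bounded monotone
#' curve with an upper age asymptote `u = 1/a`), not binary-outcome
#' regression.
#'
#' Two fitting modes:
#' * **fixed asymptote** (`asymptote = <years>`): with `u` known the model
#'   linearises — `ln(1/CA - 1/u) = ln(b) + DMS * ln(c)` — and ordinary
#'   least squares on the transformed response gives `b` and `c` directly
#'   (`a = 1/u`).
#' * **free asymptote** (`asymptote = "free"`, default): full nonlinear
#'   least squares over `(a, b, c)` (Levenberg-Marquardt), initialised from
#'   the linearised fit with a provisional asymptote `1.05 * max(CA)`,
#'   constrained to `a, b > 0` and `0 < c < 1`.
#'
#' Fit quality is reported on the age scale: `r_squared = 1 - SSE/SST`
#' (which for the nonlinear fit can in principle be negative, hence only
#' bounded above by 1) and Spearman's rank correlation between score and
#' age.
#'
#' @param dms maturity scores
#' @param ca chronological ages (years), all positive
#' @param asymptote `"free"` or a fixed upper age asymptote in years
#' @return a `calibration_result` list: `model` ([prediction_model()]),
#'   `r_squared`, `spearman_rho`, `fit_method`, `n`, `converged`
#' @examples
#' m <- default_prediction_models()$M
#' dms <- seq(10, 95, length.out = 50)
#' fit <- fit_logistic_growth(dms, predict_age(dms, m))
#' fit$model
#' @export
fit_logistic_growth <- function(dms, ca, asymptote = "free") {
  if (length(dms) != length(ca)) {
    stop_dentalage("dms and ca must have equal length", "insufficient_data")
  }
  if (length(unique(dms)) < 3) {
    stop_dentalage("need at least 3 distinct maturity scores",
                   "insufficient_data")
  }
  if (any(ca <= 0)) {
    stop_dentalage("all ages must be positive", "invalid_input")
  }
  if (stats::var(ca) == 0) {
    stop_dentalage("constant ages: nothing to fit (SST = 0)",
                   "degenerate_response")
  }
  sex <- attr(dms, "sex") %||% "M"

  lin_fit <- function(u) {
    if (any(ca >= u)) {
      stop_dentalage(sprintf("fixed asymptote %.3f must exceed every age", u),
                     "invalid_asymptote")
    }
    y <- log(1/ca - 1/u)
    co <- stats::coef(stats::lm(y ~ dms))
    list(a = 1/u, b = exp(unname(co[1])), c = exp(unname(co[2])))
  }

  if (identical(asymptote, "free")) {
    start <- lin_fit(1.05 * max(ca))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ca ~ 1/(a + b * c^dms),
        start = start,
        lower = c(a = 1e-8, b = 1e-8, c = 1e-8),
        upper = c(a = 10, b = 100, c = 1 - 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(model = NULL, r_squared = NA_real_,
                            spearman_rho = spearman(dms, ca)$rho,
                            fit_method = "free-asymptote-nls",
                            n = length(ca), converged = FALSE),
                       class = "calibration_result"))
    }
    pars <- as.list(stats::coef(fit))
    method <- "free-asymptote-nls"
    converged <- fit$convInfo$isConv %||% TRUE
  } else {
    stopifnot(is.numeric(asymptote), length(asymptote) == 1)
    pars <- lin_fit(asymptote)
    method <- "linearized-fixed-asymptote"
    converged <- TRUE
  }
  model <- prediction_model(sex, pars$a, pars$b, pars$c)
  structure(list(model = model,
                 r_squared = r_squared(model, dms, ca),
                 spearman_rho = spearman(dms, ca)$rho,
                 fit_method = method, n = length(ca), converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("logistic growth fit (%s, n = %d, converged = %s)\n",
              x$fit_method, x$n, x$converged))
  if (!is.null(x$model)) print(x$model)
  cat(sprintf("  R^2 = %.4f, Spearman rho = %.4f\n", x$r_squared, x$spearman_rho))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (the tie-respecting definition). The
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' n-2 degrees of freedom; `exact = TRUE` enumerates all permutations of one
#' ranking (supported up to n = 8) for an exact two-sided p.
#'
#' @param x,y equal-length numeric vectors (n >= 2)
#' @param exact exact permutation p-value (n <= 8 only)
#' @return list: `rho`, `p_value`, `n`
#' @export
spearman <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 2) {
    stop_dentalage("need two equal-length vectors of at least 2 values",
                   "insufficient_data")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop_dentalage("zero variance in ranks: correlation undefined",
                   "undefined_correlation")
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) {
      stop_dentalage("exact permutation p-value supported for n <= 8",
                     "invalid_input")
    }
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx[p], ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (n > 2 && abs(rho) < 1) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else {
    p <- if (abs(rho) >= 1) 0 else NA_real_
  }
  list(rho = rho, p_value = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Coefficient of determination of a prediction model
#'
#' `R^2 = 1 - SSE/SST` on the age scale: the share of chronological-age
#' variance explained by the model's predictions from the maturity score.
#'
#' @param model a [prediction_model()]
#' @param dms maturity scores
#' @param ca observed chronological ages, not all equal
#' @return numeric scalar (at most 1; negative when the model fits worse
#'   than the mean)
#' @export
r_squared <- function(model, dms, ca) {
  if (length(dms) != length(ca) || length(ca) < 2) {
    stop_dentalage("need at least 2 pairs", "insufficient_data")
  }
  sst <- sum((ca - mean(ca))^2)
  if (sst == 0) {
    stop_dentalage("constant ages: R^2 undefined (SST = 0)",
                   "degenerate_response")
  }
  1 - sum((ca - predict_age(dms, model))^2) / sst
}
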