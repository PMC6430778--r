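#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; ages reported to two decimals in
#' clinical tables conventionally round half up. Exposed because the rounding
#' convention for chronological age is a documented, configurable choice.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half away from zero
#' @examples
#' round_half_up(c(2.345, 2.344, -2.345), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dentalage <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dentalage_error")))
}

check_sex <- function(sex) {
  if (!all(sex %in% c("M", "F"))) {
    stop_dentalage("sex must be 'M' or 'F'", "invalid_sex")
  }
  sex
}
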