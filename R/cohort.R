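#' Chronological age in decimal years
#'
#' Age at the radiograph: exact day count between date of birth and date of
#' radiograph divided by 365.25, reported to two decimal places. Rounding is
#' half-up by default, the convention of clinical age tables; pass
#' `rounding = "half-even"` for IEEE rounding or `digits = NA` to skip
#' rounding.
#'
#' @param dob date of birth (`Date` or ISO 8601 string)
#' @param dor date of radiograph (`Date` or ISO 8601 string)
#' @param digits decimal places (default 2); `NA` for full precision
#' @param rounding `"half-up"` (default) or `"half-even"`
#' @return numeric vector of ages in decimal years
#' @examples
#' compute_chronological_age("2010-01-01", "2017-07-01") # 7.50
#' @export
compute_chronological_age <- function(dob, dor, digits = 2,
                                      rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  dob <- as.Date(dob)
  dor <- as.Date(dor)
  if (anyNA(dob) || anyNA(dor)) {
    stop_dentalage("unparseable date in dob/dor", "invalid_record")
  }
  if (any(dor < dob)) {
    stop_dentalage("date of radiograph precedes date of birth", "invalid_record")
  }
  ca <- as.numeric(dor - dob) / 365.25
  if (is.na(digits)) return(ca)
  if (rounding == "half-up") round_half_up(ca, digits) else round(ca, digits)
}

#' Yearly age groups of the study design
#'
#' Eight one-year strata from 3 to 11 years, each closed at its lower bound
#' and open at its upper bound (exclusive-type class intervals), labelled
#' `"3 to <4"` ... `"10 to <11"`.
#'
#' @return data frame with columns `label`, `lower`, `upper`
#' @export
age_groups <- function() {
  lower <- 3:10
  data.frame(label = sprintf("%d to <%d", lower, lower + 1),
             lower = lower, upper = lower + 1)
}

#' Assign a chronological age to its study age group
#'
#' @param ca numeric vector of ages in decimal years, each in `[3, 11)`
#' @return factor of group labels (levels in age order)
#' @examples
#' assign_age_group(c(3, 4, 10.99))
#' @export
assign_age_group <- function(ca) {
  if (any(ca < 3 | ca >= 11)) {
    stop_dentalage("age outside the studied range [3, 11)", "age_out_of_range")
  }
  g <- age_groups()
  factor(g$label[floor(ca) - 2L], levels = g$label)
}

#' Read a cohort table
#'
#' One row per child: `child_id`, `sex` (M/F), `dob`, `dor` (ISO 8601), and
#' per-tooth stage columns `t31`..`t37`, `t41`..`t47` holding a stage code or
#' empty for a missing/unreadable tooth. All cells are validated; offending
#' cells are reported with row numbers. In `strict` mode (default) any invalid
#' row aborts the read; in lenient mode invalid rows are collected into an
#' exclusion report instead.
#'
#' @param path CSV file path
#' @param strict abort on first validation pass failure (default `TRUE`)
#' @return a cohort data frame (attribute `"excluded"` carries the exclusion
#'   report in lenient mode)
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("child_id", "sex", "dob", "dor")
  if (!all(need %in% names(raw))) {
    stop_dentalage(sprintf("cohort file lacks column(s): %s",
                           paste(setdiff(need, names(raw)), collapse = ", ")),
                   "invalid_cohort_file")
  }
  tc <- c(tooth_cols("left"), tooth_cols("right"))
  for (col in setdiff(tc, names(raw))) raw[[col]] <- rep(NA_character_, nrow(raw))
  raw[tc] <- lapply(raw[tc], function(x) {
    x[is.na(x) | x == ""] <- NA_character_
    as.character(x)
  })

  problems <- character(0)
  bad_rows <- integer(0)
  note <- function(i, msg) {
    problems <<- c(problems, sprintf("row %d: %s", i, msg))
    bad_rows <<- union(bad_rows, i)
  }
  dob <- as.Date(rep(NA, nrow(raw)))
  dor <- dob
  for (i in seq_len(nrow(raw))) {
    if (!raw$sex[i] %in% c("M", "F")) note(i, sprintf("unknown sex code '%s'", raw$sex[i]))
    d1 <- tryCatch(as.Date(raw$dob[i]), error = function(e) NA)
    d2 <- tryCatch(as.Date(raw$dor[i]), error = function(e) NA)
    if (is.na(d1)) note(i, sprintf("unparseable dob '%s'", raw$dob[i]))
    if (is.na(d2)) note(i, sprintf("unparseable dor '%s'", raw$dor[i]))
    if (!is.na(d1) && !is.na(d2) && d2 < d1) note(i, "dor precedes dob")
    dob[i] <- d1; dor[i] <- d2
    for (col in tc) {
      v <- raw[[col]][i]
      if (!is.na(v) && !v %in% stage_codes()) {
        note(i, sprintf("unknown stage letter '%s' in %s", v, col))
      }
    }
  }
  if (length(problems) && strict) {
    stop_dentalage(paste0("cohort validation failed:\n  ",
                          paste(problems, collapse = "\n  ")),
                   "invalid_cohort_file")
  }
  cohort <- data.frame(child_id = raw$child_id, sex = raw$sex,
                       dob = dob, dor = dor, raw[tc])
  if (length(bad_rows)) {
    keep <- setdiff(seq_len(nrow(cohort)), bad_rows)
    excluded <- data.frame(child_id = raw$child_id[bad_rows],
                           reason = "validation",
                           value = vapply(bad_rows, function(i) {
                             paste(grep(sprintf("^row %d:", i), problems, value = TRUE),
                                   collapse = "; ")
                           }, character(1)))
    cohort <- cohort[keep, , drop = FALSE]
    rownames(cohort) <- NULL
    attr(cohort, "excluded") <- excluded
  }
  cohort
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: ISO 8601 dates, empty cells for absent stages.
#'
#' @param cohort cohort data frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$dob <- format(as.Date(out$dob), "%Y-%m-%d")
  out$dor <- format(as.Date(out$dor), "%Y-%m-%d")
  keep <- intersect(c("child_id", "sex", "dob", "dor",
                      tooth_cols("left"), tooth_cols("right")), names(out))
  utils::write.csv(out[keep], path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Exclude records whose estimated dental age is below a minimum
#'
#' The study range starts at an estimated dental age of 2.5 years; records
#' whose radiographic interpretation yields a lower estimate are excluded
#' after estimation, with an exclusion log.
#'
#' @param cohort cohort data frame with an `eda` column set on every row
#' @param min_eda minimum estimated dental age in years (default 2.5)
#' @return list with elements `retained` (cohort rows kept), `excluded`
#'   (rows removed) and `log` (data frame `child_id`, `reason`, `value`)
#' @export
exclude_below_min_age <- function(cohort, min_eda = 2.5) {
  if (!"eda" %in% names(cohort) || anyNA(cohort$eda)) {
    stop_dentalage("every record must have an estimated dental age (eda)",
                   "missing_eda")
  }
  drop <- cohort$eda < min_eda
  log <- data.frame(child_id = cohort$child_id[drop],
                    reason = rep(sprintf("eda below %.2f", min_eda), sum(drop)),
                    value = cohort$eda[drop])
  list(retained = cohort[!drop, , drop = FALSE],
       excluded = cohort[drop, , drop = FALSE],
       log = log)
}
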