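#' Load a sex-specific self-weighted score table
#'
#' The maturity score of a child is the sum, over the seven left mandibular
#' teeth, of a sex-specific "self-weighted" score for the tooth's developmental
#' stage. A score table is shipped as editable data (CSV with columns `sex`,
#' `tooth`, `stage`, `score`), never hard-coded: users may substitute any
#' edition of the reference tables. Loading validates the structural
#' invariants and fails loudly, naming the offending cell:
#'
#' * every (sex, tooth, stage) cell present: 2 sexes x 7 teeth x 9 stages;
#' * stage `"0"` (pre-calcification) scores 0;
#' * scores non-decreasing with stage within each (sex, tooth);
#' * full-maturity normalisation: the seven stage-H scores sum to 100 per sex.
#'
#' The table packaged with dentalage
#' (`system.file("extdata", "score_table_synthetic.csv", package = "dentalage")`)
#' is a synthetic stand-in with the structure of the published seven-tooth
#' tables (weights and within-tooth progressions chosen to be realistic), not
#' a transcription of any published edition.
#'
#' @param path CSV path; default is the packaged synthetic table
#' @return a `score_table` object (data frame plus lookup array)
#' @examples
#' tab <- load_score_table()
#' score_lookup(tab, "M", 36, "H")
#' @export
load_score_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "score_table_synthetic.csv",
                                package = "dentalage")
  df <- utils::read.csv(path, colClasses = c("character", "integer",
                                             "character", "numeric"))
  as_score_table(df)
}

#' Build a score table from a data frame
#'
#' @param df data frame with columns `sex`, `tooth`, `stage`, `score`
#' @return validated `score_table` object
#' @rdname load_score_table
#' @export
as_score_table <- function(df) {
  need <- c("sex", "tooth", "stage", "score")
  if (!all(need %in% names(df))) {
    stop_dentalage("score table needs columns sex, tooth, stage, score",
                   "invalid_score_table")
  }
  arr <- array(NA_real_, dim = c(2, 7, 9),
               dimnames = list(sex = c("M", "F"),
                               tooth = as.character(fdi_teeth()),
                               stage = stage_codes()))
  for (i in seq_len(nrow(df))) {
    sx <- df$sex[i]; to <- as.character(df$tooth[i]); st <- df$stage[i]
    if (!sx %in% c("M", "F") || !to %in% dimnames(arr)$tooth ||
        !st %in% stage_codes()) {
      stop_dentalage(sprintf("score table: unknown cell (%s, %s, %s)", sx, to, st),
                     "invalid_score_table")
    }
    arr[sx, to, st] <- df$score[i]
  }
  miss <- which(is.na(arr), arr.ind = TRUE)
  if (nrow(miss)) {
    lab <- apply(miss[1, , drop = FALSE], 1, function(ix) {
      paste(dimnames(arr)$sex[ix[1]], dimnames(arr)$tooth[ix[2]],
            dimnames(arr)$stage[ix[3]])
    })
    stop_dentalage(sprintf("score table: missing cell(s), first is (%s)", lab),
                   "invalid_score_table")
  }
  if (any(arr[, , "0"] != 0)) {
    stop_dentalage("score table: stage '0' must score 0", "invalid_score_table")
  }
  for (sx in c("M", "F")) for (to in dimnames(arr)$tooth) {
    if (any(diff(arr[sx, to, ]) < 0)) {
      stop_dentalage(sprintf("score table: scores decrease with stage at (%s, %s)",
                             sx, to), "invalid_score_table")
    }
  }
  for (sx in c("M", "F")) {
    tot <- sum(arr[sx, , "H"])
    if (abs(tot - 100) > 1e-9) {
      stop_dentalage(sprintf(
        "score table: full-maturity sum for sex %s is %.6f, not 100", sx, tot),
        "invalid_score_table")
    }
  }
  structure(list(table = df[c("sex", "tooth", "stage", "score")], scores = arr),
            class = "score_table")
}

#' Look up a stage score
#'
#' @param table a `score_table`
#' @param sex `"M"` or `"F"` (vectorised)
#' @param tooth FDI code 31-37 (vectorised)
#' @param stage stage code (vectorised)
#' @return numeric score(s)
#' @export
score_lookup <- function(table, sex, tooth, stage) {
  stopifnot(inherits(table, "score_table"))
  table$scores[cbind(check_sex(sex), as.character(tooth), stage)]
}

#' @export
print.score_table <- function(x, ...) {
  cat("Demirjian-style self-weighted score table: 2 sexes x 7 teeth x 9 stages\n")
  cat("full-maturity sums:",
      sprintf("M=%.2f F=%.2f", sum(x$scores["M", , "H"]), sum(x$scores["F", , "H"])),
      "\n")
  invisible(x)
}
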