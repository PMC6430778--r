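#' Resolve the stage of a scored tooth, with contralateral substitution
#'
#' The left mandibular tooth is read when present; when missing or
#' unreadable, the stage of its right-side (contralateral) counterpart is
#' used instead (31<->41 ... 37<->47). Substitution never leaves the
#' mandible. When both sides are absent the tooth is unscorable and an error
#' identifying the child and tooth is raised — mirroring the study's
#' exclusion of radiographs on which a target tooth cannot be scored.
#'
#' @param record one cohort row (data frame row or named list) with stage
#'   columns `t31`..`t37`, `t41`..`t47`
#' @param tooth FDI code of a left mandibular tooth (31-37)
#' @return the resolved stage code
#' @export
resolve_stage <- function(record, tooth) {
  if (!tooth %in% fdi_teeth()) {
    stop_dentalage("tooth must be one of FDI 31-37", "invalid_tooth")
  }
  left <- record[[paste0("t", tooth)]]
  if (!is.null(left) && !is.na(left)) return(left)
  right <- record[[paste0("t", contralateral(tooth))]]
  if (!is.null(right) && !is.na(right)) return(right)
  stop_dentalage(sprintf("child %s: tooth %d unscorable on both sides",
                         as.character(record[["child_id"]] %||% "?"), tooth),
                 "unscorable_tooth")
}

#' Dental maturity score of one child
#'
#' Sum over the seven teeth of the sex-specific stage score of the resolved
#' stage; ranges from 0 (no visible calcification anywhere) to 100 (all seven
#' apices closed).
#'
#' @param record one cohort row with `sex` and stage columns
#' @param table a [score_table][load_score_table]
#' @return maturity score in `[0, 100]`
#' @export
compute_dms <- function(record, table) {
  stages <- vapply(fdi_teeth(), function(to) resolve_stage(record, to),
                   character(1))
  sum(score_lookup(table, rep(record[["sex"]], 7), fdi_teeth(), stages))
}

#' Maturity scores for a whole cohort
#'
#' Applies [compute_dms()] to every record; records with an unscorable tooth
#' (both sides absent) are split off into an exclusion log rather than
#' aborting the run.
#'
#' @param cohort cohort data frame
#' @param table a [score_table][load_score_table]
#' @return list: `cohort` (scorable rows with a `dms` column added) and
#'   `log` (data frame `child_id`, `reason`, `value` for unscorable records)
#' @export
score_cohort <- function(cohort, table) {
  dms <- rep(NA_real_, nrow(cohort))
  why <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch(compute_dms(cohort[i, ], table),
                    unscorable_tooth = function(e) conditionMessage(e))
    if (is.character(res)) why[i] <- res else dms[i] <- res
  }
  ok <- !is.na(dms)
  out <- cohort[ok, , drop = FALSE]
  out$dms <- dms[ok]
  list(cohort = out,
       log = data.frame(child_id = cohort$child_id[!ok],
                        reason = rep("unscorable tooth", sum(!ok)),
                        value = why[!ok]))
}
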