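#' Demirjian developmental stage codes
#'
#' A permanent tooth is staged radiographically through eight developmental
#' stages, "A" (initial cusp calcification) to "H" (apical closure). A
#' pre-calcification state, coded `"0"`, precedes stage A. The nine codes are
#' totally ordered `0 < A < ... < H`.
#'
#' @return character vector of the nine stage codes in developmental order
#' @examples
#' stage_codes()
#' @export
stage_codes <- function() c("0", LETTERS[1:8])

#' Ordinal index of a stage code
#'
#' @param stage character vector of stage codes
#' @return integer vector: 0 for `"0"`, 1 for `"A"`, ..., 8 for `"H"`;
#'   `NA` stays `NA`
#' @examples
#' stage_index(c("0", "D", "H"))
#' @export
stage_index <- function(stage) {
  idx <- match(stage, stage_codes()) - 1L
  bad <- !is.na(stage) & is.na(idx)
  if (any(bad)) {
    stop_dentalage(
      sprintf("unknown stage code(s): %s",
              paste(unique(stage[bad]), collapse = ", ")),
      "invalid_stage")
  }
  idx
}

#' FDI codes of the scored teeth
#'
#' The seven left permanent mandibular teeth (central incisor through second
#' molar) carry the maturity score; their right-side counterparts 41-47 are
#' consulted only for contralateral substitution.
#'
#' @param side `"left"` (31-37, default) or `"right"` (41-47)
#' @return integer vector of seven FDI tooth codes
#' @export
fdi_teeth <- function(side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") 31:37 else 41:47
}

tooth_cols <- function(side = "left") paste0("t", fdi_teeth(side))

contralateral <- function(tooth) {
  stopifnot(all(tooth %in% c(31:37, 41:47)))
  ifelse(tooth > 40, tooth - 10L, tooth + 10L)
}
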