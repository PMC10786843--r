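#' Cell morphology classes
#'
#' Erythrocyte morphology is scored into three classes: `circular` (normal
#' discocytes), `elongated` (sickle forms) and `other` (all remaining
#' deformations). This ordering is fixed everywhere counts are laid out, so
#' confusion matrices from different runs are always conformable.
#'
#' @return Character vector of the three class names, in canonical order.
#' @export
#' @examples
#' cell_levels()
cell_levels <- function() {
  c("circular", "elongated", "other")
}

#' Cell classes after merging deformations
#'
#' For diagnosis support the two deformed classes are pooled: mistaking an
#' elongated cell for another deformation still flags the cell for review,
#' so the clinically meaningful split is normal vs deformed.
#'
#' @return Character vector `c("circular", "deformed")`.
#' @export
cell_levels_binary <- function() {
  c("circular", "deformed")
}

#' Parse morphology labels from text
#'
#' Case-insensitive, whitespace-trimmed parsing of label strings into the
#' canonical factor. Anything outside the three classes is an error rather
#' than an `NA`: a silently dropped vote would corrupt downstream confusion
#' counts.
#'
#' @param x Character vector of labels.
#' @param allow_na If `TRUE`, `NA` inputs pass through (used for consensus
#'   columns where `NA` encodes "no answer"); otherwise `NA` is an error.
#' @return Factor with levels [cell_levels()].
#' @export
#' @examples
#' parse_cell_labels(c("Circular", " ELONGATED", "other"))
parse_cell_labels <- function(x, allow_na = FALSE) {
  lv <- cell_levels()
  cleaned <- tolower(trimws(as.character(x)))
  bad <- !(cleaned %in% lv) & !(allow_na & is.na(x))
  if (any(bad)) {
    offenders <- unique(as.character(x)[bad])
    stop(
      "unknown cell label(s): ",
      paste(sprintf("'%s'", utils::head(offenders, 5L)), collapse = ", "),
      " (expected one of: ", paste(lv, collapse = ", "), ")",
      call. = FALSE
    )
  }
  factor(cleaned, levels = lv)
}
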