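#' Build a confusion matrix from truth and predictions
#'
#' Rows are ground-truth classes, columns predicted classes, in the fixed
#' order of [cell_levels()] (or [cell_levels_binary()] for merged tables).
#' Predictions may be `NA` ("no answer" from a failed consensus): these are
#' tallied in a dedicated `no-answer` column, which every metric treats as
#' an incorrect prediction.
#'
#' @param data Data frame holding one scored cell per row.
#' @param truth Column of true labels (factor or character over
#'   [cell_levels()]).
#' @param estimate Column of predicted labels; may contain `NA`.
#' @return A `cell_confusion` object: an integer matrix with attributes
#'   `labels` (class order) and `has_na` (whether a no-answer column is
#'   present).
#' @export
#' @examples
#' d <- tibble::tibble(
#'   truth = c("circular", "circular", "other"),
#'   pred  = c("circular", NA, "elongated")
#' )
#' cell_confusion(d, truth, pred)
cell_confusion <- function(data, truth, estimate) {
  tr <- parse_cell_labels(dplyr::pull(data, {{ truth }}), allow_na = TRUE)
  pr <- dplyr::pull(data, {{ estimate }})
  if (anyNA(tr)) {
    stop("every scored cell needs a ground-truth label", call. = FALSE)
  }
  pr <- parse_cell_labels(pr, allow_na = TRUE)
  lv <- cell_levels()
  counts <- table(factor(tr, levels = lv), factor(pr, levels = lv))
  m <- matrix(as.integer(counts), nrow = length(lv),
              dimnames = list(truth = lv, predicted = lv))
  n_na <- as.integer(table(factor(tr[is.na(pr)], levels = lv)))
  has_na <- any(n_na > 0L)
  if (has_na) {
    m <- cbind(m, `no-answer` = n_na)
  }
  new_cell_confusion(m, labels = lv, has_na = has_na)
}

#' Construct a confusion matrix from raw counts
#'
#' For when counts are already tabulated (e.g. a published summary table).
#'
#' @param counts Square integer matrix (rows truth, columns predicted), with
#'   optionally one extra trailing column of no-answer counts.
#' @param labels Class labels in order; default [cell_levels()] for 3
#'   columns, [cell_levels_binary()] for 2.
#' @return A `cell_confusion` object.
#' @export
as_cell_confusion <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  nr <- nrow(counts)
  has_na <- ncol(counts) == nr + 1L
  if (!has_na && ncol(counts) != nr) {
    stop("counts must be L x L or L x (L+1) with a trailing no-answer column",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- switch(as.character(nr),
      "3" = cell_levels(),
      "2" = cell_levels_binary(),
      stop("supply labels for a ", nr, "-class matrix", call. = FALSE)
    )
  }
  dimnames(counts) <- list(
    truth = labels,
    predicted = if (has_na) c(labels, "no-answer") else labels
  )
  new_cell_confusion(matrix(as.integer(counts), nrow = nr,
                            dimnames = dimnames(counts)),
                     labels = labels, has_na = has_na)
}

new_cell_confusion <- function(m, labels, has_na) {
  structure(m, labels = labels, has_na = has_na,
            class = c("cell_confusion", "matrix", "array"))
}

#' @export
print.cell_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted), n =",
      sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

# Square class-by-class block (drops the no-answer column).
cc_square <- function(cm) {
  lab <- attr(cm, "labels")
  unclass(cm)[, seq_along(lab), drop = FALSE]
}

# No-answer counts per true class (zeros when absent).
cc_na_col <- function(cm) {
  lab <- attr(cm, "labels")
  if (isTRUE(attr(cm, "has_na"))) unclass(cm)[, length(lab) + 1L]
  else stats::setNames(rep(0L, length(lab)), lab)
}

#' Merge deformed classes into one
#'
#' Collapses the three-class confusion matrix to circular vs deformed by
#' summing the elongated and other rows and columns. Totals and the
#' circular row/column marginals are preserved; a no-answer column, if
#' present, is carried through by summing its deformed rows.
#'
#' @param cm A 3-class `cell_confusion`.
#' @return A 2-class `cell_confusion` with labels [cell_levels_binary()].
#' @export
merge_to_binary <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  lab <- attr(cm, "labels")
  if (length(lab) != 3L) {
    stop("merge_to_binary expects a 3-class matrix", call. = FALSE)
  }
  sq <- cc_square(cm)
  m2 <- matrix(
    c(sq[1, 1], sum(sq[1, 2:3]),
      sum(sq[2:3, 1]), sum(sq[2:3, 2:3])),
    nrow = 2, byrow = TRUE,
    dimnames = list(truth = cell_levels_binary(),
                    predicted = cell_levels_binary())
  )
  has_na <- isTRUE(attr(cm, "has_na"))
  if (has_na) {
    na_col <- cc_na_col(cm)
    m2 <- cbind(m2, `no-answer` = c(na_col[1], sum(na_col[2:3])))
  }
  new_cell_confusion(matrix(as.integer(m2), nrow = 2, dimnames = dimnames(m2)),
                     labels = cell_levels_binary(), has_na = has_na)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix into long counts
#'
#' @param x A `cell_confusion`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `predicted`, `n`.
#' @method tidy cell_confusion
#' @export
tidy.cell_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "predicted", "n")
  tibble::as_tibble(df)
}

#' One-row metric summary of a confusion matrix
#'
#' @param x A `cell_confusion`.
#' @param ... Unused.
#' @return One-row tibble: `n_cells`, `overall_accuracy`, `sds_score`,
#'   `cba`, `mcc`, `f_measure` (macro F1). For 3-class input `mcc` is the
#'   multiclass (Gorodkin) form; for 2-class the binary form.
#' @method glance cell_confusion
#' @export
glance.cell_confusion <- function(x, ...) {
  tibble::tibble(
    n_cells = sum(x),
    overall_accuracy = overall_accuracy(x),
    sds_score = sds_score(x),
    cba = cba_macro_recall(x),
    mcc = if (length(attr(x, "labels")) == 2L) mcc_binary(x)
          else mcc_multiclass(x),
    f_measure = f_measure(x, variant = "macro")
  )
}
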