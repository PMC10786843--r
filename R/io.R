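#' Read a vote table from CSV
#'
#' Expects header `cell_id,worker_id,label`, one vote per row. Labels are
#' parsed case-insensitively; unknown labels and duplicate (cell, worker)
#' pairs are errors, never dropped.
#'
#' @param path CSV path.
#' @param k Panel size to enforce (`NULL` to skip the exactly-k check).
#' @return Vote tibble.
#' @export
read_votes <- function(path, k = 5L) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("cell_id", "worker_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("vote CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(k)) {
    df$label <- parse_cell_labels(df$label)
    tibble::as_tibble(df[required])
  } else {
    validate_votes(df[required], k = k)
  }
}

#' Read a ground-truth table from CSV
#'
#' Expects header `cell_id,label`; duplicate cells are an error.
#'
#' @param path CSV path.
#' @return Truth tibble (`cell_id`, `label` factor).
#' @export
read_truth <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(c("cell_id", "label"), names(df))
  if (length(missing) > 0) {
    stop("truth CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id) > 0) {
    stop("duplicate cell_id in truth table", call. = FALSE)
  }
  df$label <- parse_cell_labels(df$label)
  tibble::as_tibble(df[c("cell_id", "label")])
}

#' Write a vote or truth table to CSV
#'
#' @param x Tibble with a `label` column (factor or character).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(x, path) {
  x <- tibble::as_tibble(x)
  x$label <- as.character(x$label)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Write consensus outcomes to CSV
#'
#' Columns `cell_id,consensus_label,agreement,configuration`; no-answer
#' cells get `NA` in `consensus_label` and 0 agreement.
#'
#' @param outcomes Output of [consensus_votes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(outcomes, path) {
  out <- outcomes
  out$consensus_label <- as.character(out$consensus_label)
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read consensus outcomes written by [write_consensus()]
#'
#' @param path CSV path.
#' @return Outcomes tibble.
#' @export
read_consensus <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = "c", consensus_label = "c",
      agreement = "i", configuration = "c"
    ),
    progress = FALSE
  )
  df$consensus_label <- parse_cell_labels(df$consensus_label,
                                          allow_na = TRUE)
  tibble::as_tibble(df)
}

#' Write a confusion matrix to CSV
#'
#' First column holds the truth labels, remaining columns the predicted
#' classes (plus `no-answer` when present); integer counts only.
#'
#' @param cm A `cell_confusion`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "cell_confusion"))
  df <- tibble::as_tibble(unclass(cm), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(truth = attr(cm, "labels")), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion()]
#'
#' @param path CSV path.
#' @return A `cell_confusion`.
#' @export
read_confusion <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(truth = "c",
                                                      .default = "i"),
                        progress = FALSE)
  m <- as.matrix(df[setdiff(names(df), "truth")])
  as_cell_confusion(m, labels = df$truth)
}
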