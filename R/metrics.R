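#' Per-class accuracy (recall)
#'
#' Fraction of each true class that was predicted correctly: diagonal count
#' over row sum. No-answer predictions sit in the row sum and never on the
#' diagonal, so they count as incorrect. A class with no ground-truth cells
#' has undefined accuracy and is reported as `NA`, not 0.
#'
#' @param cm A `cell_confusion`.
#' @return Tibble with columns `class`, `correct`, `total`, `accuracy`.
#' @export
per_class_accuracy <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  sq <- cc_square(cm)
  total <- rowSums(unclass(cm))
  correct <- diag(sq)
  tibble::tibble(
    class = attr(cm, "labels"),
    correct = as.integer(correct),
    total = as.integer(total),
    accuracy = ifelse(total > 0, correct / total, NA_real_)
  )
}

#' Overall accuracy
#'
#' Trace over total, no-answer predictions counting as errors.
#'
#' @param cm A `cell_confusion`.
#' @return Fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  sum(diag(cc_square(cm))) / sum(cm)
}

#' Sickle-cell diagnosis support score
#'
#' A triage-oriented score for the three-way morphology task. Confusing the
#' two deformed classes with each other (elongated vs other) is harmless —
#' either way the specialist is alerted — so those confusions join the true
#' positives in the numerator. Every error involving the circular (normal)
#' class is dangerous and goes in the denominator:
#' `SDS = N / (N + Ec)` with
#' `N  = TP(all classes) + (elongated -> other) + (other -> elongated)` and
#' `Ec = (circular -> deformed) + (deformed -> circular)`.
#'
#' On a merged 2-class matrix the deformed-vs-deformed terms vanish and the
#' score coincides with the 3-class value of the parent matrix.
#'
#' A no-answer vote on a circular cell counts in `Ec` (the cell is flagged
#' without cause); a no-answer on a deformed cell enters neither `N` nor
#' `Ec` — the score only weighs circular-related mistakes.
#'
#' @param cm A 3-class or 2-class `cell_confusion`.
#' @return Fraction in \[0, 1\]; `NA` if the denominator is zero.
#' @export
sds_score <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  sq <- cc_square(cm)
  L <- nrow(sq)
  n_tp <- sum(diag(sq))
  # deformed-vs-deformed confusions are forgiven
  n_within <- if (L == 3L) sq[2, 3] + sq[3, 2] else 0L
  ec <- sum(sq[1, -1]) + sum(sq[-1, 1]) + unname(cc_na_col(cm)[1])
  num <- n_tp + n_within
  den <- num + ec
  if (den == 0) return(NA_real_)
  num / den
}

#' Class-balance accuracy, macro-recall form
#'
#' Unweighted mean of per-class recalls: the accuracy a balanced test set
#' would show, immune to the dominance of circular cells. This is the
#' variant whose values match published class-balance-accuracy figures for
#' this task; see [cba_mosley()] for the literature's max-marginal form.
#'
#' @param cm A `cell_confusion`; every class must have ground-truth cells.
#' @return Fraction in \[0, 1\].
#' @export
cba_macro_recall <- function(cm) {
  acc <- per_class_accuracy(cm)
  if (anyNA(acc$accuracy)) {
    stop("class with zero ground-truth cells; macro recall undefined",
         call. = FALSE)
  }
  mean(acc$accuracy)
}

#' Class-balance accuracy, max-marginal (Mosley) form
#'
#' Mean over classes of `diag / max(row sum, column sum)`, penalizing both
#' missed cells and over-prediction of a class. Kept as the literature
#' definition; it does not equal [cba_macro_recall()] in general.
#'
#' @param cm A `cell_confusion`.
#' @return Fraction in \[0, 1\].
#' @export
cba_mosley <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  sq <- cc_square(cm)
  denom <- pmax(rowSums(unclass(cm)), colSums(sq))
  if (any(denom == 0)) {
    stop("class with empty row and column; CBA undefined", call. = FALSE)
  }
  mean(diag(sq) / denom)
}

#' Matthews correlation coefficient, binary
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the first
#' class (circular) as positive; 0 when any denominator factor is 0. A
#' no-answer column, if present, is treated as a non-positive prediction
#' (the detector did not call the cell circular).
#'
#' @param cm A 2-class `cell_confusion`.
#' @return Value in \[-1, 1\].
#' @export
mcc_binary <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  sq <- cc_square(cm)
  if (nrow(sq) != 2L) stop("mcc_binary expects a 2-class matrix", call. = FALSE)
  na_col <- cc_na_col(cm)
  # no-answer = predicted-not-this-class for both classes
  tp <- sq[1, 1]; fn <- sq[1, 2] + na_col[1]
  fp <- sq[2, 1]; tn <- sq[2, 2] + na_col[2]
  denom <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(denom == 0)) return(0)
  unname((tp * tn - fp * fn) / sqrt(prod(denom)))
}

#' Matthews correlation coefficient, multiclass (Gorodkin)
#'
#' `(c*s - sum(t_k p_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, `t` row sums and `p` column sums.
#' Reduces to [mcc_binary()] for 2x2 input. A no-answer column is treated
#' as an extra predicted category (never correct).
#'
#' @param cm A `cell_confusion`.
#' @return Value in \[-1, 1\]; 0 on a degenerate (zero-variance) margin.
#' @export
mcc_multiclass <- function(cm) {
  stopifnot(inherits(cm, "cell_confusion"))
  m <- unclass(cm)
  L <- length(attr(cm, "labels"))
  if (ncol(m) > L) {
    # square up: no-answer becomes its own predicted class with no truth row
    m <- rbind(m, `no-answer` = 0L)
  }
  s <- sum(m)
  c0 <- sum(diag(m))
  t <- rowSums(m)
  p <- colSums(m)
  d1 <- s^2 - sum(p^2)
  d2 <- s^2 - sum(t^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  (c0 * s - sum(t * p)) / sqrt(d1) / sqrt(d2)
}

#' F-measure
#'
#' Per-class F1 = 2PR/(P+R) combined as the macro mean, the
#' support-weighted mean, or the micro (pooled-count) form. Classes with
#' `P + R = 0` contribute 0. Micro-F equals overall accuracy for
#' single-label classification without a no-answer column.
#'
#' @param cm A `cell_confusion`.
#' @param variant One of `"macro"`, `"weighted"`, `"micro"`.
#' @return Fraction in \[0, 1\].
#' @export
f_measure <- function(cm, variant = c("macro", "weighted", "micro")) {
  stopifnot(inherits(cm, "cell_confusion"))
  variant <- match.arg(variant)
  sq <- cc_square(cm)
  tp <- diag(sq)
  support <- rowSums(unclass(cm))   # includes no-answer in the truth margin
  pred_tot <- colSums(sq)
  if (variant == "micro") {
    prec <- sum(tp) / sum(pred_tot)
    rec <- sum(tp) / sum(support)
    if (prec + rec == 0) return(0)
    return(2 * prec * rec / (prec + rec))
  }
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  switch(variant,
    macro = mean(f1),
    weighted = sum(f1 * support) / sum(support)
  )
}

#' Score consensus outcomes against ground truth
#'
#' Joins consensus outcomes to expert labels, optionally restricts to an
#' agreement stratum, and computes the full metric suite on both the
#' 3-class and the merged 2-class confusion matrix.
#'
#' @param truth Data frame `cell_id`, `label` of expert labels.
#' @param outcomes Output of [consensus_votes()]. Every outcome cell must
#'   have a truth label.
#' @param stratum `"all"` (default; no-answer cells kept and counted as
#'   errors — the "aggregated" convention), `"consensus"` (only cells that
#'   reached a consensus), or an agreement level (`5`, `4`, `3`).
#' @return One-row tibble per matrix flavor: `stratum`, `classes`,
#'   `n_cells`, `overall_accuracy`, `sds_score`, `cba`, `mcc`, `f_measure`,
#'   plus a list-column `confusion` with the `cell_confusion` object and a
#'   list-column `by_class` of per-class accuracies. Empty strata yield a
#'   row with `n_cells = 0` and `NA` metrics.
#' @export
consensus_report <- function(truth, outcomes, stratum = "all") {
  truth <- tibble::as_tibble(truth)
  truth$label <- parse_cell_labels(truth$label)
  missing <- setdiff(outcomes$cell_id, truth$cell_id)
  if (length(missing) > 0) {
    stop("outcome cell(s) without ground truth, e.g.: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  scored <- outcomes |>
    dplyr::inner_join(truth, by = "cell_id") |>
    dplyr::rename(truth_label = "label")

  scored <- switch(as.character(stratum),
    all = scored,
    consensus = dplyr::filter(scored, .data$agreement > 0L),
    dplyr::filter(scored, .data$agreement == as.integer(stratum))
  )
  stratum_name <- as.character(stratum)

  if (nrow(scored) == 0) {
    return(tibble::tibble(
      stratum = stratum_name, classes = c("3-class", "2-class"),
      n_cells = 0L, overall_accuracy = NA_real_, sds_score = NA_real_,
      cba = NA_real_, mcc = NA_real_, f_measure = NA_real_,
      confusion = list(NULL, NULL), by_class = list(NULL, NULL)
    ))
  }

  cm3 <- cell_confusion(scored, .data$truth_label, .data$consensus_label)
  cm2 <- merge_to_binary(cm3)
  # sparse strata can miss whole classes; undefined metrics become NA
  safely_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  report_row <- function(cm, classes) {
    tibble::tibble(
      stratum = stratum_name, classes = classes, n_cells = sum(cm),
      overall_accuracy = overall_accuracy(cm),
      sds_score = safely_na(sds_score(cm)),
      cba = safely_na(cba_macro_recall(cm)),
      mcc = if (length(attr(cm, "labels")) == 2L) mcc_binary(cm)
            else mcc_multiclass(cm),
      f_measure = f_measure(cm, "macro"),
      confusion = list(cm), by_class = list(per_class_accuracy(cm))
    )
  }
  dplyr::bind_rows(report_row(cm3, "3-class"), report_row(cm2, "2-class"))
}

#' Regression of worker accuracy on labeling volume
#'
#' Ordinary least squares of per-worker accuracy on the number of cells the
#' worker classified. A slope indistinguishable from zero means prolific
#' workers are no more (or less) accurate than occasional ones.
#'
#' @param workers Data frame with columns `n_classified` and `accuracy`,
#'   one row per worker.
#' @return The fitted `lm` object (use [generics::tidy()] on it for slope
#'   and intercept with standard errors).
#' @export
worker_volume_regression <- function(workers) {
  workers <- tibble::as_tibble(workers)
  stopifnot(all(c("n_classified", "accuracy") %in% names(workers)))
  if (nrow(workers) < 2L || length(unique(workers$n_classified)) < 2L) {
    stop("need at least two workers with distinct volumes", call. = FALSE)
  }
  stats::lm(accuracy ~ n_classified, data = workers)
}

#' Per-worker accuracy and volume table
#'
#' Convenience summary feeding [worker_volume_regression()]: for each
#' worker, the number of cells they classified and the fraction they got
#' right against ground truth.
#'
#' @param votes Vote table (`cell_id`, `worker_id`, `label`).
#' @param truth Truth table (`cell_id`, `label`).
#' @return Tibble `worker_id`, `n_classified`, `accuracy`.
#' @export
worker_accuracy <- function(votes, truth) {
  truth <- tibble::as_tibble(truth)
  truth$label <- parse_cell_labels(truth$label)
  tibble::as_tibble(votes) |>
    dplyr::mutate(label = parse_cell_labels(.data$label)) |>
    dplyr::inner_join(truth, by = "cell_id", suffix = c("", "_truth")) |>
    dplyr::group_by(.data$worker_id) |>
    dplyr::summarise(
      n_classified = dplyr::n(),
      accuracy = mean(.data$label == .data$label_truth),
      .groups = "drop"
    )
}

#' Round half-up to a fixed number of decimals
#'
#' Published tables round halves away from zero (87.745 -> 87.75), unlike
#' R's banker's rounding. Used when formatting fractions as table-style
#' percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
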