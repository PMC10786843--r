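#' Predicted consensus accuracy under worker independence
#'
#' If each of `k` independent workers labels a cell of a given class
#' correctly with probability `alpha`, the consensus (plurality with
#' threshold `floor(k/2) + 1`) is correct whenever at least that many
#' workers are right. The predicted consensus accuracy is the binomial
#' tail
#' \deqn{\sum_{j = \lfloor k/2 \rfloor + 1}^{k} \binom{k}{j}
#'       \alpha^j (1-\alpha)^{k-j},}
#' which for the default panel of five is
#' \eqn{\alpha^5 + 5\alpha^4(1-\alpha) + 10\alpha^3(1-\alpha)^2}.
#'
#' The model ignores how wrong votes split among wrong labels (a 2-2-1
#' split of errors could still deny consensus to fewer than 3 correct
#' votes); it is the simple at-least-threshold-correct approximation.
#' Correlated worker errors — e.g. a shared hard cell — push observed
#' consensus accuracy below this prediction.
#'
#' @param alpha Per-worker accuracy for the class, in \[0, 1\]. Vectorized.
#' @param k Panel size, odd, >= 3 (default 5).
#' @return Predicted consensus accuracy, same length as `alpha`.
#' @export
#' @examples
#' estimate_consensus_accuracy(2676 / 3085)  # circular cells, 5 workers
#' estimate_consensus_accuracy(0.5)          # symmetric: exactly 0.5
estimate_consensus_accuracy <- function(alpha, k = 5L) {
  k <- check_panel_size(k)
  if (any(is.na(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  stats::pbinom(consensus_threshold(k) - 1L, size = k, prob = alpha,
                lower.tail = FALSE)
}

#' Compare predicted and observed consensus accuracy per class
#'
#' Takes per-worker accuracy per class from the individual-vote confusion
#' matrix (diagonal over row sum), predicts consensus accuracy under the
#' independence model, and sets it against the accuracy the consensus
#' actually achieved. A systematic positive gap (estimated > observed) is
#' the signature of correlated worker errors.
#'
#' @param cm_individual `cell_confusion` of individual votes (one count per
#'   vote, so row sums are `k` times the per-class cell counts).
#' @param truth Truth table (`cell_id`, `label`).
#' @param outcomes Output of [consensus_votes()] on the same cells.
#' @param k Panel size used for the individual matrix (default 5).
#' @return Tibble per class: `class`, `alpha`, `acc_estimated`,
#'   `acc_observed`, `gap` (= estimated - observed). No-answer outcomes
#'   count against observed accuracy.
#' @export
compare_estimate_vs_observed <- function(cm_individual, truth, outcomes,
                                         k = 5L) {
  stopifnot(inherits(cm_individual, "cell_confusion"))
  truth <- tibble::as_tibble(truth)
  truth$label <- parse_cell_labels(truth$label)
  if (!setequal(truth$cell_id, outcomes$cell_id)) {
    stop("truth and outcomes must cover the same cells", call. = FALSE)
  }
  ind <- per_class_accuracy(cm_individual)
  # the individual matrix carries k votes per cell
  n_cells_by_class <- truth |> dplyr::count(.data$label, .drop = FALSE)
  if (!all(ind$total == n_cells_by_class$n * k)) {
    stop("individual matrix row sums must equal k votes per cell per class",
         call. = FALSE)
  }
  obs <- consensus_report(truth, outcomes, stratum = "all") |>
    dplyr::filter(.data$classes == "3-class") |>
    dplyr::pull("by_class")
  obs <- obs[[1]]
  tibble::tibble(
    class = ind$class,
    alpha = ind$accuracy,
    acc_estimated = estimate_consensus_accuracy(ind$accuracy, k = k),
    acc_observed = obs$accuracy,
    gap = .data$acc_estimated - .data$acc_observed
  )
}
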