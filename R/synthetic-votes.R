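#' Worker response profile
#'
#' A worker's labeling behavior as a 3x3 row-stochastic matrix: row = true
#' class, column = emitted label, diagonal = the worker's per-class
#' accuracy alpha.
#'
#' @param worker_id Identifier.
#' @param response_matrix 3x3 matrix, rows summing to 1 (within 1e-9), in
#'   the order of [cell_levels()].
#' @return A `worker_profile` list.
#' @export
worker_profile <- function(worker_id, response_matrix) {
  response_matrix <- as.matrix(response_matrix)
  if (!all(dim(response_matrix) == c(3L, 3L))) {
    stop("response_matrix must be 3x3", call. = FALSE)
  }
  if (any(response_matrix < 0) ||
      any(abs(rowSums(response_matrix) - 1) > 1e-9)) {
    stop("response_matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  dimnames(response_matrix) <- list(truth = cell_levels(),
                                    emitted = cell_levels())
  structure(list(worker_id = as.character(worker_id),
                 response_matrix = response_matrix),
            class = "worker_profile")
}

#' Worker profiles anchored to an observed confusion matrix
#'
#' Builds `k` identical profiles whose response rows are the normalized
#' rows of an individual-vote confusion matrix, so simulations inherit the
#' empirically observed error structure (e.g. circular-cell errors split
#' between elongated and other in the observed proportion).
#'
#' @param cm 3-class `cell_confusion` of individual votes.
#' @param k Number of workers (default 5).
#' @return List of `k` [worker_profile()] objects.
#' @export
profiles_from_confusion <- function(cm, k = 5L) {
  stopifnot(inherits(cm, "cell_confusion"), length(attr(cm, "labels")) == 3L)
  sq <- cc_square(cm)
  rm <- sweep(sq, 1, rowSums(sq), "/")
  purrr::map(seq_len(k), ~ worker_profile(sprintf("w%02d", .x), rm))
}

#' Equal-accuracy worker profiles
#'
#' `k` workers who label every class correctly with probability `alpha`,
#' splitting errors evenly between the two wrong classes — the homogeneous
#' regime the independence model describes exactly.
#'
#' @param alpha Per-class accuracy in \[0, 1\].
#' @param k Number of workers.
#' @return List of [worker_profile()] objects.
#' @export
uniform_profiles <- function(alpha, k = 5L) {
  stopifnot(alpha >= 0, alpha <= 1)
  off <- (1 - alpha) / 2
  rm <- matrix(off, 3, 3)
  diag(rm) <- alpha
  purrr::map(seq_len(k), ~ worker_profile(sprintf("w%02d", .x), rm))
}

#' Shared cell-difficulty model
#'
#' The minimal mechanism for correlated worker errors: a fraction
#' `pi_hard` of cells is latently "hard"; on a hard cell every worker's
#' diagonal accuracy is multiplied by `hard_penalty` (off-diagonal mass
#' rescaled proportionally to keep rows stochastic). Because the latent is
#' shared, workers err together on the same cells, and observed consensus
#' accuracy falls below the independence-model prediction.
#'
#' @param pi_hard Fraction of hard cells, in \[0, 1\].
#' @param hard_penalty Multiplier on diagonal accuracy for hard cells, in
#'   \[0, 1\].
#' @return A `difficulty_model` list.
#' @export
difficulty_model <- function(pi_hard, hard_penalty) {
  stopifnot(pi_hard >= 0, pi_hard <= 1, hard_penalty >= 0, hard_penalty <= 1)
  structure(list(pi_hard = pi_hard, hard_penalty = hard_penalty),
            class = "difficulty_model")
}

# Degrade a response row for a hard cell: diagonal times penalty,
# off-diagonal rescaled to fill the freed mass (uniform split if the row
# had no error mass at all).
degrade_row <- function(row, true_idx, penalty) {
  d <- row[true_idx] * penalty
  off <- row[-true_idx]
  out <- row
  out[true_idx] <- d
  if (sum(off) > 0) {
    out[-true_idx] <- off * (1 - d) / sum(off)
  } else {
    out[-true_idx] <- (1 - d) / 2
  }
  out
}

#' Simulate worker votes on labeled cells
#'
#' Draws one vote per (cell, worker). Without a difficulty model, votes
#' are independent across workers given the true class: each worker's vote
#' is a draw from their response-matrix row. With a [difficulty_model()],
#' a per-cell hard/easy latent is drawn once and shared by all workers,
#' inducing positively correlated errors. Deterministic given `seed`.
#'
#' @param truth Data frame `cell_id`, `label` (true classes).
#' @param workers List of [worker_profile()] objects (panel of size
#'   `length(workers)`).
#' @param difficulty Optional [difficulty_model()].
#' @param seed Integer seed (mandatory).
#' @return Vote table tibble `cell_id`, `worker_id`, `label`, valid input
#'   for [consensus_votes()]. A `hard` attribute (logical per cell) is
#'   attached when a difficulty model is used.
#' @export
simulate_votes <- function(truth, workers, difficulty = NULL, seed) {
  truth <- tibble::as_tibble(truth)
  if (nrow(truth) == 0) stop("truth table is empty", call. = FALSE)
  truth$label <- parse_cell_labels(truth$label)
  stopifnot(length(workers) >= 1,
            all(purrr::map_lgl(workers, inherits, "worker_profile")))
  lv <- cell_levels()
  n <- nrow(truth)
  true_idx <- as.integer(truth$label)

  with_seed(seed, {
    hard <- if (is.null(difficulty)) rep(FALSE, n)
            else stats::runif(n) < difficulty$pi_hard
    votes <- purrr::map(workers, function(w) {
      rm <- w$response_matrix
      emitted <- integer(n)
      for (cls in 1:3) {
        for (h in c(FALSE, TRUE)) {
          sel <- true_idx == cls & hard == h
          if (!any(sel)) next
          row <- rm[cls, ]
          if (h) row <- degrade_row(row, cls, difficulty$hard_penalty)
          emitted[sel] <- sample.int(3L, sum(sel), replace = TRUE, prob = row)
        }
      }
      tibble::tibble(cell_id = truth$cell_id, worker_id = w$worker_id,
                     label = lv[emitted])
    })
    out <- dplyr::bind_rows(votes)
    if (!is.null(difficulty)) {
      attr(out, "hard") <- stats::setNames(hard, truth$cell_id)
    }
    out
  })
}

#' Bundled reference tables from a crowd-labeling benchmark
#'
#' Summary tables of a crowd-labeling study of 848 expert-labeled smear
#' cells, each annotated by 5 workers: the individual-vote confusion
#' matrix (one count per vote; 4240 votes), the per-class consensus
#' (correct, total) pairs, and the agreement-stratum counts. These anchor
#' the metric suite and the independence model to observed data and seed
#' the simulator's default error structure.
#'
#' @return List with `individual_cm` (3-class `cell_confusion`),
#'   `individual_cm_binary` (its merged form), `consensus_pairs` (tibble
#'   `class`, `correct`, `total`), `agreement_counts` (tibble `stratum`,
#'   `n`: 463 / 226 / 135 full-, 4-, 3-agreement cells and 24 no-answer),
#'   and `n_cells` (848).
#' @export
crowd_benchmark_tables <- function() {
  individual <- as_cell_confusion(matrix(
    c(2676, 58, 351,
      48, 614, 243,
      69, 28, 153),
    nrow = 3, byrow = TRUE
  ))
  list(
    individual_cm = individual,
    individual_cm_binary = merge_to_binary(individual),
    consensus_pairs = tibble::tibble(
      class = cell_levels(),
      correct = c(566L, 128L, 32L),
      total = c(617L, 181L, 50L)
    ),
    agreement_counts = tibble::tibble(
      stratum = c("5-agree", "4-agree", "3-agree", "no-answer"),
      n = c(463L, 226L, 135L, 24L)
    ),
    n_cells = 848L
  )
}
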