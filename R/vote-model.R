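#' Validate a vote table
#'
#' A vote table has one row per (cell, worker) pair: columns `cell_id`,
#' `worker_id`, `label`. Every cell must carry exactly `k` votes and no
#' worker may vote twice on the same cell.
#'
#' @param votes Data frame with columns `cell_id`, `worker_id`, `label`.
#' @param k Panel size; every cell must have exactly `k` votes. Odd, >= 3.
#' @return The validated table as a tibble, with `label` parsed to the
#'   canonical factor, invisibly usable downstream.
#' @export
validate_votes <- function(votes, k = 5L) {
  check_panel_size(k)
  required <- c("cell_id", "worker_id", "label")
  missing <- setdiff(required, names(votes))
  if (length(missing) > 0) {
    stop("vote table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  votes <- tibble::as_tibble(votes)
  votes$label <- parse_cell_labels(votes$label)

  dup <- votes |>
    dplyr::count(.data$cell_id, .data$worker_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("duplicate (cell_id, worker_id) vote(s), e.g.: ",
         paste(utils::head(paste0(dup$cell_id, "/", dup$worker_id), 5L),
               collapse = ", "),
         call. = FALSE)
  }

  sizes <- votes |> dplyr::count(.data$cell_id)
  off <- sizes |> dplyr::filter(.data$n != k)
  if (nrow(off) > 0) {
    stop("every cell must have exactly ", k, " votes; offending cell(s): ",
         paste(utils::head(off$cell_id, 5L), collapse = ", "),
         call. = FALSE)
  }
  votes
}

check_panel_size <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 3L || k %% 2L == 0L) {
    stop("panel size k must be a single odd integer >= 3, got: ", k,
         call. = FALSE)
  }
  invisible(as.integer(k))
}

#' Plurality threshold for a panel
#'
#' The minimum number of agreeing votes that yields a consensus:
#' `floor(k/2) + 1`, i.e. 3 of 5 for the default panel.
#'
#' @param k Odd panel size.
#' @return Integer threshold.
#' @export
consensus_threshold <- function(k = 5L) {
  k <- check_panel_size(k)
  k %/% 2L + 1L
}

# Signature of sorted vote counts, e.g. "3-1-1"; zero counts omitted.
config_signature <- function(counts) {
  counts <- sort(counts[counts > 0L], decreasing = TRUE)
  paste(counts, collapse = "-")
}

#' Aggregate worker votes by plurality consensus
#'
#' Each cell is labeled by a panel of `k` workers. If the most-voted class
#' reaches `floor(k/2) + 1` votes (3 of 5), that class is the consensus;
#' otherwise the cell gets no answer (`NA`). For `k = 5` and three classes
#' the only no-answer configuration is the 2-2-1 split.
#'
#' @param votes Vote table (`cell_id`, `worker_id`, `label`); validated with
#'   [validate_votes()].
#' @param k Panel size (odd, default 5).
#' @return A tibble with one row per cell: `cell_id`, `consensus_label`
#'   (factor over [cell_levels()], `NA` = no answer), `agreement` (votes for
#'   the winning class; 0 when no answer) and `configuration` (the sorted
#'   vote-count signature such as `"5"`, `"4-1"`, `"3-1-1"`, `"3-2"`,
#'   `"2-2-1"`).
#' @export
#' @examples
#' votes <- tibble::tibble(
#'   cell_id = rep("c1", 5), worker_id = paste0("w", 1:5),
#'   label = c("circular", "circular", "circular", "elongated", "other")
#' )
#' consensus_votes(votes)
consensus_votes <- function(votes, k = 5L) {
  k <- check_panel_size(k)
  votes <- validate_votes(votes, k = k)
  threshold <- consensus_threshold(k)
  lv <- cell_levels()

  votes |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      .counts = list(tabulate(.data$label, nbins = length(lv))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      configuration = purrr::map_chr(.data$.counts, config_signature),
      .top = purrr::map_int(.data$.counts, ~ max(.x)),
      .win = purrr::map_int(.data$.counts, ~ which.max(.x)),
      consensus_label = factor(
        ifelse(.data$.top >= threshold, lv[.data$.win], NA_character_),
        levels = lv
      ),
      agreement = ifelse(.data$.top >= threshold, .data$.top, 0L)
    ) |>
    dplyr::select("cell_id", "consensus_label", "agreement", "configuration")
}

#' Stratify consensus outcomes by agreement level
#'
#' Partitions cells by how many workers backed the winning label (the
#' reliability signal of the consensus): full agreement (5), 4, 3, or no
#' answer. Every cell lands in exactly one stratum.
#'
#' @param outcomes Output of [consensus_votes()].
#' @param k Panel size the outcomes came from; taken from the
#'   configuration signatures when `NULL` (their parts sum to `k`).
#' @return The outcomes tibble with a `stratum` factor column added; levels
#'   are `"<k>-agree"`, ..., `"3-agree"`, `"no-answer"`.
#' @export
stratify_agreement <- function(outcomes, k = NULL) {
  if (anyDuplicated(outcomes$cell_id) > 0) {
    stop("duplicate cell_id in outcomes", call. = FALSE)
  }
  if (is.null(k)) {
    k <- if (nrow(outcomes) > 0) {
      sum(as.integer(strsplit(outcomes$configuration[1], "-")[[1]]))
    } else 5L
  }
  levels_all <- c(paste0(seq(k, consensus_threshold(k)), "-agree"),
                  "no-answer")
  outcomes |>
    dplyr::mutate(
      stratum = factor(
        ifelse(.data$agreement > 0L,
               paste0(.data$agreement, "-agree"), "no-answer"),
        levels = levels_all
      )
    )
}

#' Count cells per agreement stratum
#'
#' @param outcomes Output of [consensus_votes()].
#' @param k Panel size (see [stratify_agreement()]).
#' @return Tibble `stratum`, `n`; strata with zero cells are kept so counts
#'   always sum to the number of cells.
#' @export
agreement_counts <- function(outcomes, k = NULL) {
  stratify_agreement(outcomes, k = k) |>
    dplyr::count(.data$stratum, .drop = FALSE)
}
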