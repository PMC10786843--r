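#' End-to-end analysis pipeline
#'
#' Runs the full chain — vote ingestion (or seeded simulation), plurality
#' consensus, agreement stratification and metric reporting — and writes
#' the report files. Outputs are staged in a temporary directory and moved
#' into place only when every stage has succeeded, so a failed run leaves
#' no partial reports.
#'
#' @param config Named list:
#'   * `votes`, `truth`: paths to input CSVs, **or**
#'   * `simulate`: list with `n_cells`, optional `class_mix`, `alpha` (for
#'     [uniform_profiles()]) or `profiles`, optional `difficulty`
#'     ([difficulty_model()]) — inputs are then simulated;
#'   * `k`: panel size (default 5);
#'   * `out_dir`: output directory (created if needed);
#'   * `seed`: integer, required when simulating;
#'   * `strata`: report strata (default `c("all", "consensus", "5", "4",
#'     "3")`).
#' @return Tibble of metric reports (one row per stratum and class
#'   flavor), invisibly; files `consensus.csv`, `confusion_3class.csv`,
#'   `confusion_2class.csv`, `metrics.csv` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  k <- config$k %||% 5L
  strata <- config$strata %||% c("all", "consensus", "5", "4", "3")
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(config$seed)) {
      stop("config$seed is required when simulating", call. = FALSE)
    }
    n_cells <- sim$n_cells %||% stop("simulate$n_cells is required",
                                     call. = FALSE)
    class_mix <- sim$class_mix %||% c(0.7, 0.2, 0.1)
    truth <- with_seed(config$seed, tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      label = sample(cell_levels(), n_cells, replace = TRUE,
                     prob = class_mix)
    ))
    profiles <- sim$profiles %||% uniform_profiles(sim$alpha %||% 0.8, k = k)
    votes <- simulate_votes(truth, profiles, difficulty = sim$difficulty,
                            seed = config$seed + 1L)
  } else {
    if (is.null(config$votes) || is.null(config$truth)) {
      stop("config needs either simulate or votes + truth paths",
           call. = FALSE)
    }
    votes <- read_votes(config$votes, k = k)
    truth <- read_truth(config$truth)
  }
  if (nrow(votes) == 0) stop("empty vote table", call. = FALSE)

  outcomes <- consensus_votes(votes, k = k)
  report <- purrr::map(strata, ~ consensus_report(truth, outcomes,
                                                  stratum = .x)) |>
    dplyr::bind_rows()
  cm3 <- cell_confusion(
    outcomes |> dplyr::inner_join(truth, by = "cell_id"),
    .data$label, .data$consensus_label
  )

  # stage everything, then move atomically
  stage <- tempfile("crowdcell_stage_")
  dir.create(stage, recursive = TRUE)
  write_consensus(outcomes, file.path(stage, "consensus.csv"))
  write_confusion(cm3, file.path(stage, "confusion_3class.csv"))
  write_confusion(merge_to_binary(cm3), file.path(stage, "confusion_2class.csv"))
  flat <- report |> dplyr::select(-"confusion", -"by_class")
  readr::write_csv(flat, file.path(stage, "metrics.csv"), progress = FALSE)

  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  message("pipeline: ", nrow(outcomes), " cells, ", nrow(votes), " votes, ",
          "reports written to ", config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
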