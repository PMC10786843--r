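# Build a one-cell vote table from a vector of label strings.
panel <- function(labels, cell = "cell1") {
  tibble::tibble(
    cell_id = cell,
    worker_id = paste0("w", seq_along(labels)),
    label = labels
  )
}

# Vote table for many cells: `panels` is a list of label vectors.
panel_table <- function(panels) {
  dplyr::bind_rows(purrr::imap(panels, ~ panel(.x, cell = sprintf("c%04d", .y))))
}

# Exhaustive plurality oracle, independent of the package implementation:
# tally by brute-force comparison against every class, consensus iff the
# best count clears the majority threshold.
oracle_consensus <- function(labels, k = length(labels)) {
  classes <- c("circular", "elongated", "other")
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  best <- which(counts == max(counts))
  threshold <- k %/% 2 + 1
  if (counts[best[1]] >= threshold) {
    list(label = classes[best[1]], agreement = counts[best[1]])
  } else {
    list(label = NA_character_, agreement = 0L)
  }
}

# All 3^k ordered panels over the three classes.
all_panels <- function(k = 5) {
  classes <- c("circular", "elongated", "other")
  grid <- do.call(expand.grid, rep(list(classes), k))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

# Independence-model oracle: enumerate every correct/incorrect pattern of
# k votes and add up the probability of those with enough correct votes.
oracle_binomial_tail <- function(alpha, k) {
  grid <- do.call(expand.grid, rep(list(c(0L, 1L)), k))
  threshold <- k %/% 2 + 1
  probs <- apply(grid, 1, function(g) {
    j <- sum(g)
    if (j >= threshold) alpha^j * (1 - alpha)^(k - j) else 0
  })
  sum(probs)
}

# Reference study fixture shorthand.
bench <- crowd_benchmark_tables()

# A random valid 3-class confusion matrix (counts 0..max_n).
random_cm <- function(max_n = 50) {
  m <- matrix(sample(0:max_n, 9, replace = TRUE), 3, 3)
  # ensure no empty truth row
  diag(m) <- diag(m) + 1L
  as_cell_confusion(m)
}
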