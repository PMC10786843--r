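test_that("confusion matrix counts truth rows against predicted columns", {
  d <- tibble::tibble(
    truth = c("circular", "circular", "other"),
    pred = c("circular", NA, "elongated")
  )
  cm <- cell_confusion(d, truth, pred)
  expect_s3_class(cm, "cell_confusion")
  expect_equal(sum(cm), 3L)
  expect_equal(unclass(cm)["circular", "circular"], 1L)
  expect_equal(unclass(cm)["circular", "no-answer"], 1L)
  expect_equal(unclass(cm)["other", "elongated"], 1L)

  ident <- tibble::tibble(truth = rep(cell_levels(), c(4, 3, 3)))
  ident$pred <- ident$truth
  cmi <- cell_confusion(ident, truth, pred)
  expect_equal(diag(unclass(cmi)), c(circular = 4L, elongated = 3L, other = 3L))
  expect_equal(sum(unclass(cmi)) - sum(diag(unclass(cmi))), 0L)
})

test_that("confusion layout is canonical regardless of input row order", {
  set.seed(42)
  d <- tibble::tibble(
    truth = sample(cell_levels(), 60, replace = TRUE),
    pred = sample(cell_levels(), 60, replace = TRUE)
  )
  cm1 <- cell_confusion(d, truth, pred)
  cm2 <- cell_confusion(d[sample(nrow(d)), ], truth, pred)
  expect_identical(cm1, cm2)
})

test_that("predictions without ground truth are an error", {
  d <- tibble::tibble(truth = c("circular", NA), pred = c("circular", "other"))
  expect_error(cell_confusion(d, truth, pred), "ground-truth")
})

test_that("per-class accuracy reproduces the benchmark individual-vote rates", {
  acc <- per_class_accuracy(bench$individual_cm)
  expect_equal(round_half_up(100 * acc$accuracy, 2), c(86.74, 67.85, 61.20))
  expect_equal(acc$correct, c(2676L, 614L, 153L))
  expect_equal(acc$total, c(3085L, 905L, 250L))
})

test_that("a class with no ground-truth cells reports NA accuracy, not zero", {
  cm <- as_cell_confusion(matrix(c(3, 0, 0, 0, 0, 0, 1, 0, 2), 3, byrow = TRUE))
  acc <- per_class_accuracy(cm)
  expect_true(is.na(acc$accuracy[2]))
  expect_false(is.na(acc$accuracy[1]))
})

test_that("SDS-score forgives deformed-vs-deformed confusions only", {
  expect_equal(round_half_up(sds_score(bench$individual_cm), 4), 0.8759)
  ident <- as_cell_confusion(diag(c(5L, 5L, 5L)))
  expect_equal(sds_score(ident), 1)
  hand <- as_cell_confusion(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE))
  expect_equal(sds_score(hand), 1 / 3)
  # merging deformed classes never changes the score
  expect_equal(sds_score(merge_to_binary(bench$individual_cm)),
               sds_score(bench$individual_cm))
})

test_that("SDS-score is at least overall accuracy on any matrix", {
  set.seed(13)
  for (i in 1:50) {
    cm <- random_cm()
    expect_gte(sds_score(cm), overall_accuracy(cm))
  }
})

test_that("no-answer counts against circular cells in the SDS-score but not deformed ones", {
  # circular no-answer enters Ec
  cm_c <- as_cell_confusion(cbind(diag(c(4L, 5L, 5L)), c(1L, 0L, 0L)))
  expect_equal(sds_score(cm_c), 14 / 15)
  # deformed no-answer enters neither N nor Ec
  cm_d <- as_cell_confusion(cbind(diag(c(5L, 4L, 5L)), c(0L, 1L, 0L)))
  expect_equal(sds_score(cm_d), 1)
})

test_that("macro-recall CBA reproduces the benchmark and the Mosley form differs", {
  expect_equal(round_half_up(cba_macro_recall(bench$individual_cm), 4), 0.7193)
  expect_equal(round_half_up(cba_macro_recall(bench$individual_cm_binary), 4),
               0.8831)
  ident <- as_cell_confusion(diag(c(2L, 2L, 2L)))
  expect_equal(cba_macro_recall(ident), 1)
  expect_equal(cba_mosley(ident), 1)
  expect_equal(cba_mosley(as_cell_confusion(matrix(1L, 2, 2))), 0.5)
  # hand evaluation of the max-marginal form on the benchmark counts
  sq <- matrix(c(2676, 58, 351, 48, 614, 243, 69, 28, 153), 3, byrow = TRUE)
  hand <- mean(diag(sq) / pmax(rowSums(sq), colSums(sq)))
  expect_equal(cba_mosley(bench$individual_cm), hand)
  expect_false(isTRUE(all.equal(cba_mosley(bench$individual_cm),
                                cba_macro_recall(bench$individual_cm))))
})

test_that("binary MCC reproduces the merged benchmark value and its bounds", {
  expect_equal(round_half_up(mcc_binary(bench$individual_cm_binary), 4), 0.7194)
  expect_equal(mcc_binary(as_cell_confusion(diag(c(3L, 4L)))), 1)
  expect_equal(mcc_binary(as_cell_confusion(matrix(c(0L, 5L, 5L, 0L), 2))), -1)
  # zero margin short-circuits to 0
  expect_equal(mcc_binary(as_cell_confusion(matrix(c(3L, 0L, 0L, 0L), 2))), 0)
})

test_that("multiclass MCC reduces to binary MCC and matches the one-hot correlation oracle", {
  set.seed(23)
  for (i in 1:20) {
    m2 <- matrix(sample(1:30, 4), 2)
    cm2 <- as_cell_confusion(m2)
    expect_equal(mcc_multiclass(cm2), mcc_binary(cm2))
  }
  # oracle: Gorodkin's statistic equals the Pearson correlation between
  # one-hot encodings of truth and prediction, expanded to samples
  for (i in 1:20) {
    cm <- random_cm()
    sq <- unclass(cm)
    truth <- rep(rep(1:3, each = 3), times = as.vector(t(sq)))
    pred <- rep(rep(1:3, times = 3), times = as.vector(t(sq)))
    tt <- stats::model.matrix(~ factor(truth, levels = 1:3) - 1)
    pp <- stats::model.matrix(~ factor(pred, levels = 1:3) - 1)
    num <- sum(diag(stats::cov(tt, pp)))
    den <- sqrt(sum(diag(stats::cov(tt)))) * sqrt(sum(diag(stats::cov(pp))))
    expect_equal(mcc_multiclass(cm), num / den, tolerance = 1e-10)
  }
  expect_equal(mcc_multiclass(as_cell_confusion(diag(c(2L, 3L, 4L)))), 1)
})

test_that("F-measure variants match longhand precision/recall arithmetic", {
  ident <- as_cell_confusion(diag(c(2L, 3L, 4L)))
  for (v in c("macro", "weighted", "micro")) {
    expect_equal(f_measure(ident, v), 1)
  }
  set.seed(31)
  for (i in 1:20) {
    cm <- random_cm()
    sq <- unclass(cm)
    prec <- diag(sq) / colSums(sq)
    rec <- diag(sq) / rowSums(sq)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    f1[is.na(f1)] <- 0
    expect_equal(f_measure(cm, "macro"), mean(f1))
    expect_equal(f_measure(cm, "weighted"), sum(f1 * rowSums(sq)) / sum(sq))
    expect_equal(f_measure(cm, "micro"), overall_accuracy(cm))
  }
})

test_that("merging to two classes pools the deformed rows and columns", {
  m2 <- merge_to_binary(bench$individual_cm)
  expect_equal(unclass(m2),
               matrix(c(2676L, 409L, 117L, 1038L), 2, byrow = TRUE,
                      dimnames = list(truth = cell_levels_binary(),
                                      predicted = cell_levels_binary())),
               ignore_attr = TRUE)
  expect_equal(sum(m2), sum(bench$individual_cm))
  # circular marginals preserved
  expect_equal(unclass(m2)[1, 1], unclass(bench$individual_cm)[1, 1])
  expect_equal(sum(unclass(m2)[1, ]), sum(unclass(bench$individual_cm)[1, ]))
  expect_equal(sum(unclass(m2)[, 1]), sum(unclass(bench$individual_cm)[, 1]))
  # identity and zero matrices are fixed points up to pooling
  expect_equal(unclass(merge_to_binary(as_cell_confusion(diag(c(1L, 1L, 1L))))),
               matrix(c(1L, 0L, 0L, 2L), 2, byrow = TRUE), ignore_attr = TRUE)
  expect_equal(sum(merge_to_binary(as_cell_confusion(matrix(0L, 3, 3)))), 0L)
  # no-answer column carried through
  cm_na <- as_cell_confusion(cbind(diag(c(2L, 2L, 2L)), c(1L, 1L, 0L)))
  m2_na <- merge_to_binary(cm_na)
  expect_equal(unclass(m2_na)[, "no-answer"], c(circular = 1L, deformed = 1L))
})

test_that("consensus_report fills every metric and respects strata", {
  # all-correct unanimous set: every metric 1
  truth <- tibble::tibble(cell_id = sprintf("c%02d", 1:9),
                          label = rep(cell_levels(), each = 3))
  votes <- simulate_votes(truth, uniform_profiles(1), seed = 1)
  outcomes <- consensus_votes(votes)
  rep_all <- consensus_report(truth, outcomes, "all")
  expect_equal(nrow(rep_all), 2)
  expect_equal(rep_all$overall_accuracy, c(1, 1))
  expect_equal(rep_all$sds_score, c(1, 1))
  expect_equal(rep_all$cba, c(1, 1))
  expect_equal(rep_all$mcc, c(1, 1))
  expect_equal(rep_all$f_measure, c(1, 1))

  # strata are a partition: cell counts add up to the full set
  set.seed(5)
  truth2 <- tibble::tibble(cell_id = sprintf("c%03d", 1:300),
                           label = sample(cell_levels(), 300, replace = TRUE))
  votes2 <- simulate_votes(truth2, uniform_profiles(0.6), seed = 5)
  outcomes2 <- consensus_votes(votes2)
  n_by_stratum <- vapply(c("5", "4", "3"), function(s) {
    r <- consensus_report(truth2, outcomes2, s)
    r$n_cells[r$classes == "3-class"]
  }, numeric(1))
  n_consensus <- consensus_report(truth2, outcomes2, "consensus")$n_cells[1]
  n_all <- consensus_report(truth2, outcomes2, "all")$n_cells[1]
  expect_equal(sum(n_by_stratum), n_consensus)
  expect_equal(n_all, 300)
  # no-answer cells count in the denominator of the aggregated accuracy
  n_na <- sum(is.na(outcomes2$consensus_label))
  r_all3 <- consensus_report(truth2, outcomes2, "all")
  r_cons3 <- consensus_report(truth2, outcomes2, "consensus")
  expect_equal(
    r_all3$overall_accuracy[1],
    r_cons3$overall_accuracy[1] * (300 - n_na) / 300
  )
})

test_that("an empty stratum yields a flagged empty report", {
  truth <- tibble::tibble(cell_id = "c1", label = "circular")
  outcomes <- consensus_votes(panel(rep("circular", 5), cell = "c1"))
  r <- consensus_report(truth, outcomes, "3")
  expect_equal(unique(r$n_cells), 0L)
  expect_true(all(is.na(r$overall_accuracy)))
})

test_that("outcomes without ground truth are an error", {
  truth <- tibble::tibble(cell_id = "cX", label = "circular")
  outcomes <- consensus_votes(panel(rep("circular", 5), cell = "c1"))
  expect_error(consensus_report(truth, outcomes), "without ground truth")
})

test_that("volume regression recovers closed-form fits and rejects degenerate input", {
  flat <- tibble::tibble(n_classified = c(10, 20, 30), accuracy = 0.7)
  fit <- worker_volume_regression(flat)
  expect_equal(unname(stats::coef(fit)["n_classified"]), 0)
  two <- tibble::tibble(n_classified = c(10, 20), accuracy = c(0.6, 0.8))
  fit2 <- worker_volume_regression(two)
  expect_equal(unname(stats::coef(fit2)["n_classified"]), 0.02)
  expect_equal(unname(stats::coef(fit2)["(Intercept)"]), 0.4)
  expect_error(
    worker_volume_regression(tibble::tibble(n_classified = c(5, 5),
                                            accuracy = c(0.5, 0.9))),
    "distinct"
  )
})

test_that("worker accuracy summarizes votes against truth", {
  truth <- tibble::tibble(cell_id = c("a", "b"), label = c("circular", "other"))
  votes <- tibble::tibble(
    cell_id = c("a", "b", "a", "b"),
    worker_id = c("w1", "w1", "w2", "w2"),
    label = c("circular", "other", "circular", "elongated")
  )
  wa <- worker_accuracy(votes, truth)
  expect_equal(wa$accuracy[wa$worker_id == "w1"], 1)
  expect_equal(wa$accuracy[wa$worker_id == "w2"], 0.5)
  expect_equal(wa$n_classified, c(2L, 2L))
})

test_that("table-style rounding goes half-up", {
  expect_equal(round_half_up(0.86745, 4), 0.8675)
  expect_equal(round_half_up(67.845, 2), 67.85)
  expect_equal(round_half_up(18.75, 0), 19)
  expect_equal(round_half_up(-0.5, 0), -1)
})

test_that("tidy and glance summarize a confusion matrix", {
  td <- generics::tidy(bench$individual_cm)
  expect_equal(sum(td$n), 4240L)
  expect_equal(nrow(td), 9L)
  g <- generics::glance(bench$individual_cm)
  expect_equal(g$n_cells, 4240L)
  expect_equal(round_half_up(g$sds_score, 4), 0.8759)
  expect_equal(round_half_up(g$cba, 4), 0.7193)
})
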