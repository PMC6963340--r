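test_that("confusion counts follow the standard binary layout", {
  cc <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_identical(unlist(cc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  cc <- confusion(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_identical(unlist(cc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  cc <- confusion(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0))
  expect_identical(unlist(cc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 2L, fn = 1L))
  expect_error(confusion(c(1, 0), c(1)), "length mismatch")
})

test_that("the six node metrics match their defining formulas", {
  perfect <- metrics_from_confusion(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                                    c(1, 1, 0, 0), c(5, 4, -3, -6))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$f_measure, 1.00)
  expect_equal(perfect$mcc, 1.00)
  expect_equal(perfect$roc_area, 100)

  # all-negative predictions on a mixed set: degenerate conventions
  degen <- metrics_from_confusion(confusion(c(1, 1, 0, 0), c(0, 0, 0, 0)))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$mcc, 0)
  expect_equal(degen$f_measure, 0)
  expect_true(is.na(degen$roc_area)) # no scores supplied: reported absent

  m <- metrics_from_confusion(confusion(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0)))
  expect_equal(m$accuracy, 60)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 200 / 3, tolerance = 1e-9)
  expect_equal(m$mcc, 1 / 6, tolerance = 1e-9)
})

test_that("metric formulas agree with independent references on random confusion tables", {
  withr::with_seed(14, {
    for (i in 1:300) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1)
      tn <- sample(0:20, 1); fn <- sample(0:20, 1)
      if (tp + fn == 0 || tn + fp == 0) next
      y <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
      p <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
      m <- metrics_from_confusion(confusion(y, p))
      expect_equal(m$accuracy, 100 * mean(y == p), tolerance = 1e-9)
      expect_equal(m$sensitivity, 100 * tp / (tp + fn), tolerance = 1e-9)
      expect_equal(m$specificity, 100 * tn / (tn + fp), tolerance = 1e-9)
      # MCC is the Pearson correlation of the two binary vectors
      mcc_ref <- suppressWarnings(stats::cor(y, p))
      expect_equal(m$mcc, if (is.na(mcc_ref)) 0 else mcc_ref, tolerance = 1e-9)
    }
  })
})

test_that("ROC area equals the rank-statistic (Mann-Whitney) oracle", {
  withr::with_seed(15, {
    for (i in 1:25) {
      n <- 40
      y <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
      if (length(unique(y)) < 2) next
      s <- rnorm(n) + y
      m <- metrics_from_confusion(confusion(y, as.integer(s > 0)), y, s)
      r <- rank(s)
      auc_ref <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) /
        (sum(y) * sum(1 - y))
      expect_equal(m$roc_area, 100 * auc_ref, tolerance = 1e-9)
    }
  })
})

test_that("MCC flips sign under prediction inversion; accuracy survives a label swap", {
  y <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 1)
  p <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1)
  m <- metrics_from_confusion(confusion(y, p))
  m_inv <- metrics_from_confusion(confusion(y, 1 - p))
  expect_equal(m$mcc, -m_inv$mcc, tolerance = 1e-12)
  m_swap <- metrics_from_confusion(confusion(1 - y, 1 - p))
  expect_equal(m$accuracy, m_swap$accuracy, tolerance = 1e-12)
})

test_that("overall accuracy reproduces the correct-out-of-total arithmetic", {
  expect_equal(round(overall_accuracy(97, 104), 1), 93.3)
  expect_equal(overall_accuracy(0, 25), 0)
  expect_equal(overall_accuracy(25, 25), 100)
  expect_error(overall_accuracy(3, 0), "positive")
  expect_error(overall_accuracy(-1, 5), "0..n_total")
  expect_error(overall_accuracy(9, 5), "0..n_total")
})

test_that("stratified folds preserve class proportions to within one sample", {
  withr::with_seed(16, {
    y <- rep(c("a", "b", "c"), c(40, 12, 8))
  })
  for (k in c(2L, 4L, 5L)) {
    folds <- stratified_folds(y, k, seed = 3)
    for (cl in unique(y)) {
      per_fold <- tabulate(folds[y == cl], k)
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
  }
  expect_error(stratified_folds(y, 1L), "k >= 2")
})

test_that("cross-validation pools fold confusions that conserve the sample count", {
  sim <- separable_sim(seed = 21, classes = 2L)
  X <- log_tpm(sim$matrix)
  y01 <- make_one_vs_rest_labels(sim$labels$group, 1)
  pipe <- default_pipeline(selection = selection_config(top_k = 10L, max_features = 3L))
  cv <- suppressWarnings(stratified_cv_evaluate(X, y01, pipe, k = 4L, seed = 8))
  for (kd in names(cv$per_kind)) {
    cm <- cv$per_kind[[kd]]$confusion
    expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, length(y01))
  }
  # leave-one-out on separable data classifies everything
  cv_loo <- suppressWarnings(stratified_cv_evaluate(
    X, y01, pipe, k = min(table(y01)), seed = 8))
  best <- max(vapply(cv_loo$per_kind, function(pk) pk$metrics$accuracy, 0))
  expect_equal(best, 100)
})

test_that("no SMOTE-synthetic row ever reaches an evaluation fold", {
  sim <- simulate_expression(small_sim_config(seed = 22))
  X <- log_tpm(sim$matrix)
  y01 <- make_one_vs_rest_labels(sim$labels$group, 2)
  pipe <- default_pipeline(selection = selection_config(top_k = 15L, max_features = 3L))
  cv <- suppressWarnings(stratified_cv_evaluate(X, y01, pipe, k = 3L, seed = 9))
  for (audit in cv$fold_audit) {
    synthetic_ids <- audit$train_provenance$row_id[
      audit$train_provenance$origin == "synthetic"]
    expect_length(intersect(audit$test_ids, synthetic_ids), 0L)
    expect_length(intersect(audit$test_ids, audit$train_provenance$row_id[
      audit$train_provenance$origin == "original"]), 0L)
  }
})

test_that("metric reports carry the six canonical columns", {
  nm <- metrics_from_confusion(confusion(c(1, 0, 1, 0), c(1, 0, 0, 0)),
                               c(1, 0, 1, 0), c(2, -1, -0.5, -2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(list("2 vs rest" = nm), overall = 75, path)
  tab <- read.delim(path, check.names = FALSE, comment.char = "#")
  expect_identical(names(tab), c("Node", "Accuracy", "Sensitivity",
                                 "Specificity", "F-Measure", "MCC", "ROC Area"))
  expect_match(readLines(path)[3], "75.0%")
})
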