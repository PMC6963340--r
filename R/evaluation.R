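# Binary classification metrics and leakage-safe stratified cross-validation.
#
# Per-node performance is summarised by six statistics: accuracy,
# sensitivity and specificity (percent), F-measure (0-1), Matthews
# correlation coefficient (-1..1), and ROC area (percent). Fold results are
# aggregated by pooling confusion counts, which matches the
# "correct out of total" arithmetic used for the overall accuracy.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred equal-length 0/1 vectors; 1 is the positive class.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("confusion(): length mismatch (%d vs %d)", length(y_true), length(y_pred))
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  structure(
    list(tp = sum(y_true == 1L & y_pred == 1L),
         fp = sum(y_true == 0L & y_pred == 1L),
         tn = sum(y_true == 0L & y_pred == 0L),
         fn = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts"
  )
}

#' The six node metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and ROC area are reported in percent;
#' F-measure in 0-1; MCC in -1..1. Zero-denominator conventions: MCC and
#' F-measure fall back to 0. The ROC area is computed from ranked decision
#' scores by trapezoidal integration (ties handled by midpoint ranks) and
#' is reported as `NA` when no scores are supplied — never fabricated.
#'
#' @param cc a [confusion()] result.
#' @param y_true optional 0/1 truth vector for the ROC curve.
#' @param scores optional decision scores aligned with `y_true` (higher
#'   means more positive).
#' @return list of class `node_metrics` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `f_measure`, `mcc`, `roc_area`.
#' @export
metrics_from_confusion <- function(cc, y_true = NULL, scores = NULL) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  acc <- if (n > 0) (tp + tn) / n else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  denom <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  mcc <- if (denom > 0) (as.double(tp) * tn - as.double(fp) * fn) / denom else 0
  roc <- NA_real_
  if (!is.null(scores) && !is.null(y_true) && length(unique(y_true)) == 2L) {
    roc <- as.numeric(pROC::auc(pROC::roc(
      response = as.integer(y_true), predictor = as.numeric(scores),
      levels = c(0L, 1L), direction = "<", quiet = TRUE
    ))) * 100
  }
  structure(
    list(accuracy = 100 * acc, sensitivity = 100 * sens,
         specificity = 100 * spec, f_measure = f, mcc = mcc, roc_area = roc),
    class = "node_metrics"
  )
}

#' Overall accuracy as a percentage
#'
#' Total correctly classified samples divided by the total number of
#' samples, times 100.
#'
#' @param n_correct number correctly classified (0..n_total).
#' @param n_total total number of samples (> 0).
#' @return percentage.
#' @examples
#' overall_accuracy(97, 104)  # 93.3 at one decimal
#' @export
overall_accuracy <- function(n_correct, n_total) {
  if (n_total <= 0) stopf("overall_accuracy(): n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) {
    stopf("overall_accuracy(): n_correct must be in 0..n_total")
  }
  100 * n_correct / n_total
}

#' Stratified fold assignment
#'
#' Samples of each class are shuffled (seeded) and dealt round-robin into
#' `k` folds, so per-fold class proportions are within one sample of the
#' global proportions.
#'
#' @param y class vector.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  if (k < 2L) stopf("stratified CV requires k >= 2")
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(as.character(y)))) {
      idx <- which(as.character(y) == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Leakage-safe stratified cross-validation of the node pipeline
#'
#' For each fold, the training portion is rebalanced (NCL + SMOTE) and
#' hybrid feature selection is re-run on it; classifiers are fitted on the
#' rebalanced, selected training data and evaluated on the untouched test
#' fold. Synthetic rows therefore exist only inside training folds; the
#' returned per-fold provenance makes that auditable. Fold metrics are
#' aggregated by pooling confusion counts (per-fold metrics are also
#' returned).
#'
#' @param X samples x features numeric matrix.
#' @param y binary 0/1 label vector.
#' @param pipeline list with elements `resampling` (a
#'   [resampling_config()]), `selection` (a [selection_config()]), and
#'   `classifier_kinds` (character vector).
#' @param k outer folds; reduced with a warning when the smaller class has
#'   fewer than `k` samples.
#' @param seed RNG seed.
#' @return list of class `cv_result`: `per_kind` (for each classifier kind:
#'   pooled `metrics`, pooled `confusion`, pooled `scores`/`truth`,
#'   per-fold metrics), `folds`, `fold_audit` (per fold: test sample ids,
#'   training provenance, selected features), `k`.
#' @export
stratified_cv_evaluate <- function(X, y, pipeline = default_pipeline(),
                                   k = 10L, seed = 1L) {
  y <- as.integer(y)
  n_min <- min(table(y))
  if (length(unique(y)) != 2L) stopf("stratified_cv_evaluate(): y must be binary with both classes present")
  if (n_min < k) {
    warnf("smallest class has %d samples; folds reduced from %d to %d", n_min, k, n_min)
    k <- n_min
  }
  if (k < 2L) stopf("smallest class has fewer than 2 samples; stratified CV impossible")
  folds <- stratified_folds(y, k, seed = derive_seed(seed, 11L))
  kinds <- pipeline$classifier_kinds
  if (is.null(rownames(X))) rownames(X) <- sprintf("row_%04d", seq_len(nrow(X)))

  acc <- lapply(kinds, function(kd) list(y = integer(0), pred = integer(0),
                                         score = numeric(0), fold_metrics = list()))
  names(acc) <- kinds
  audit <- vector("list", k)

  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    rcfg <- pipeline$resampling
    rcfg$seed <- derive_seed(seed, 1000L + f)
    rs <- rebalance(X[tr, , drop = FALSE], y[tr], rcfg)
    sel <- select_features(rs$X, rs$y, pipeline$selection,
                           seed = derive_seed(seed, 2000L + f),
                           provenance = rs$provenance)
    audit[[f]] <- list(
      test_ids = rownames(X)[te],
      train_provenance = rs$provenance,
      removed = rs$removed,
      selected = sel$selected
    )
    for (kd in kinds) {
      clf <- fit_node_classifier(kd, rs$X[, sel$selected, drop = FALSE], rs$y)
      sc <- predict_node_score(clf, X[te, , drop = FALSE])
      pr <- as.integer(sc > 0)
      cm <- confusion(y[te], pr)
      acc[[kd]]$y <- c(acc[[kd]]$y, y[te])
      acc[[kd]]$pred <- c(acc[[kd]]$pred, pr)
      acc[[kd]]$score <- c(acc[[kd]]$score, sc)
      acc[[kd]]$fold_metrics[[f]] <- metrics_from_confusion(cm, y[te], sc)
    }
  }

  per_kind <- lapply(acc, function(a) {
    cm <- confusion(a$y, a$pred)
    list(metrics = metrics_from_confusion(cm, a$y, a$score),
         confusion = cm, truth = a$y, scores = a$score,
         fold_metrics = a$fold_metrics)
  })
  structure(list(per_kind = per_kind, folds = folds, fold_audit = audit, k = k),
            class = "cv_result")
}

#' Default node pipeline specification
#'
#' @param resampling a [resampling_config()].
#' @param selection a [selection_config()].
#' @param classifier_kinds classifier kinds to fit and compare per node.
#' @return a list usable as the `pipeline` argument of
#'   [stratified_cv_evaluate()].
#' @export
default_pipeline <- function(resampling = resampling_config(),
                             selection = selection_config(),
                             classifier_kinds = node_classifier_kinds()) {
  list(resampling = resampling, selection = selection,
       classifier_kinds = classifier_kinds)
}

#' Write a per-node metrics report
#'
#' TSV (or JSON) with one row per hierarchy node and the six metric
#' columns, plus an overall-accuracy line. Percentages are printed to one
#' decimal place; full precision is kept internally.
#'
#' @param node_metrics_list named list of `node_metrics` (names = node
#'   labels).
#' @param overall overall accuracy percentage (or `NA`).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_metrics_report <- function(node_metrics_list, overall, path,
                                 format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- do.call(rbind, lapply(names(node_metrics_list), function(nm) {
    m <- node_metrics_list[[nm]]
    data.frame(
      Node = nm,
      Accuracy = round(m$accuracy, 1), Sensitivity = round(m$sensitivity, 1),
      Specificity = round(m$specificity, 1), `F-Measure` = round(m$f_measure, 2),
      MCC = round(m$mcc, 2),
      `ROC Area` = if (is.na(m$roc_area)) NA else round(m$roc_area, 1),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }))
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("# Overall accuracy: %s\n",
                if (is.na(overall)) "NA" else sprintf("%.1f%%", overall)),
        file = path, append = TRUE)
  } else {
    jsonlite::write_json(list(nodes = df, overall_accuracy = overall), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(df)
}
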