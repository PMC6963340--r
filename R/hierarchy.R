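# Greedy construction of the hierarchical one-vs-rest classification tree.
#
# At each internal node every remaining class is evaluated as
# positive-vs-rest through the full node pipeline (rebalancing + hybrid
# feature selection + classifier comparison) under stratified outer CV;
# the class with the highest cross-validated accuracy is isolated, its
# samples are removed, and construction recurses until two classes remain,
# which are separated by a final direct binary node. For C classes the
# model therefore has exactly C - 1 decision points. Isolating the
# easiest class first limits how far its errors propagate down the tree.

#' One-vs-rest binary labels
#'
#' @param y multiclass label vector.
#' @param positive_class the class to encode as 1; all others become 0.
#' @return integer 0/1 vector, sample order preserved.
#' @export
make_one_vs_rest_labels <- function(y, positive_class) {
  if (!positive_class %in% y) {
    stopf("positive class %s is not present in the label vector", positive_class)
  }
  if (all(y == positive_class)) {
    stopf("all samples belong to class %s; no negative class can be formed", positive_class)
  }
  as.integer(y == positive_class)
}

#' Hierarchy build configuration
#'
#' @param cv_folds outer stratified folds used to score candidate classes
#'   (default 10; automatically reduced, with a warning, when a class is
#'   smaller than the fold count).
#' @param classifier_kinds classifier kinds compared at every node on the
#'   same folds; the best-by-accuracy kind is retained per node.
#' @param resampling a [resampling_config()].
#' @param selection a [selection_config()].
#' @param min_class_size classes smaller than this trigger a warning that
#'   their metrics rest on very few positives (default 4, the smallest
#'   group size the method is expected to cope with).
#' @param seed global seed; all per-fold and per-stage seeds derive from it.
#' @return list of class `hierarchy_config`.
#' @export
hierarchy_config <- function(cv_folds = 10L,
                             classifier_kinds = node_classifier_kinds(),
                             resampling = resampling_config(),
                             selection = selection_config(),
                             min_class_size = 4L,
                             seed = 1L) {
  stopifnot(cv_folds >= 2L, length(classifier_kinds) >= 1L)
  structure(
    list(cv_folds = as.integer(cv_folds), classifier_kinds = classifier_kinds,
         resampling = resampling, selection = selection,
         min_class_size = as.integer(min_class_size), seed = as.integer(seed)),
    class = "hierarchy_config"
  )
}

#' Evaluate one candidate class as positive-vs-rest
#'
#' Runs the full node pipeline under stratified outer cross-validation:
#' per fold, the training portion is rebalanced and feature-selected, each
#' classifier kind is fitted and scored on the untouched test fold, and
#' fold confusions are pooled. The best classifier kind by pooled accuracy
#' is retained for the candidate.
#'
#' @param X samples x features numeric matrix.
#' @param y multiclass label vector.
#' @param candidate_class the class evaluated as positive.
#' @param config a [hierarchy_config()].
#' @return list of class `candidate_evaluation`: `candidate_class`,
#'   `metrics` (six-statistic `node_metrics` of the best kind),
#'   `classifier_kind`, `selected_features` (union over folds, sorted),
#'   `per_kind_metrics`, `cv` (the full `cv_result`).
#' @export
evaluate_candidate <- function(X, y, candidate_class, config = hierarchy_config()) {
  y01 <- make_one_vs_rest_labels(y, candidate_class)
  pipeline <- list(resampling = config$resampling, selection = config$selection,
                   classifier_kinds = config$classifier_kinds)
  cv <- stratified_cv_evaluate(X, y01, pipeline, k = config$cv_folds,
                               seed = derive_seed(config$seed, 7L * as.integer(factor(candidate_class, levels = sort(unique(y))))))
  accs <- vapply(cv$per_kind, function(pk) pk$metrics$accuracy, numeric(1L))
  best_kind <- names(accs)[which.max(accs)]  # ties keep the first-listed kind
  sel_union <- sort(unique(unlist(lapply(cv$fold_audit, `[[`, "selected"))))
  structure(
    list(candidate_class = candidate_class,
         metrics = cv$per_kind[[best_kind]]$metrics,
         classifier_kind = best_kind,
         selected_features = sel_union,
         per_kind_metrics = lapply(cv$per_kind, `[[`, "metrics"),
         cv = cv),
    class = "candidate_evaluation"
  )
}

# Refit the node pipeline on all remaining samples once a class is chosen:
# rebalance the full one-vs-rest set, select features, fit the retained
# classifier kind.
refit_node <- function(X, y01, kind, config, seed_offset) {
  rcfg <- config$resampling
  rcfg$seed <- derive_seed(config$seed, 31L + seed_offset)
  rs <- rebalance(X, y01, rcfg)
  sel <- select_features(rs$X, rs$y, config$selection,
                         seed = derive_seed(config$seed, 63L + seed_offset),
                         provenance = rs$provenance)
  clf <- fit_node_classifier(kind, rs$X[, sel$selected, drop = FALSE], rs$y)
  list(classifier = clf, selected = sel$selected, selection = sel)
}

#' Build the greedy one-vs-rest hierarchy
#'
#' @param X samples x features numeric matrix (log-scale expression).
#' @param y multiclass label vector aligned with the rows of `X`.
#' @param config a [hierarchy_config()].
#' @return list of class `hierarchy_model`: `nodes` (each with
#'   `target_class`, `other_class` (final node only), `selected_feature_ids`
#'   (the refit selection the node classifier uses), `panel_feature_ids`
#'   (the node's reported biomarker panel: the refit selection united with
#'   the features selected across the winning candidate's outer training
#'   folds — selection aggregated over resampled fits, as panels are
#'   reported), `classifier_kind`, `classifier`, `node_metrics`,
#'   `is_final`), `class_order`, `feature_ids`, `trace` (one row per
#'   candidate per level: the six metrics, classifier kind and chosen
#'   flag), and `schema_version`.
#' @export
build_hierarchy <- function(X, y, config = hierarchy_config()) {
  validate_expression_matrix_shape(X, y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stopf("build_hierarchy() needs at least 2 classes")
  small <- names(which(table(y) < config$min_class_size))
  if (length(small)) {
    warnf("class(es) %s have fewer than %d samples; their node metrics rest on very few positives",
          paste(small, collapse = ", "), config$min_class_size)
  }

  Xr <- X; yr <- y
  nodes <- list()
  class_order <- c()
  trace <- list()
  level <- 0L

  while (length(unique(yr)) > 2L) {
    level <- level + 1L
    remaining <- sort(unique(yr))
    evals <- list()
    for (cl in remaining) {
      ev <- tryCatch(evaluate_candidate(Xr, yr, cl, config), error = function(e) {
        warnf("candidate class %s skipped at level %d: %s", cl, level, conditionMessage(e))
        NULL
      })
      if (!is.null(ev)) evals[[as.character(cl)]] <- ev
    }
    if (length(evals) == 0L) stopf("all candidate evaluations failed at level %d; build aborted", level)

    stats_df <- do.call(rbind, lapply(evals, function(ev) data.frame(
      level = level, candidate_class = ev$candidate_class,
      classifier_kind = ev$classifier_kind,
      accuracy = ev$metrics$accuracy, sensitivity = ev$metrics$sensitivity,
      specificity = ev$metrics$specificity, f_measure = ev$metrics$f_measure,
      mcc = ev$metrics$mcc, roc_area = ev$metrics$roc_area,
      chosen = FALSE, stringsAsFactors = FALSE
    )))
    # greedy choice: highest accuracy; ties by sensitivity, specificity,
    # then lower class label
    ord <- order(-stats_df$accuracy, -stats_df$sensitivity,
                 -stats_df$specificity, stats_df$candidate_class)
    winner <- stats_df$candidate_class[ord[1L]]
    stats_df$chosen[stats_df$candidate_class == winner] <- TRUE
    trace[[level]] <- stats_df

    wev <- evals[[as.character(winner)]]
    y01 <- make_one_vs_rest_labels(yr, winner)
    rf <- refit_node(Xr, y01, wev$classifier_kind, config, seed_offset = level)
    nodes[[length(nodes) + 1L]] <- list(
      target_class = winner, other_class = NA,
      selected_feature_ids = rf$selected,
      panel_feature_ids = sort(union(rf$selected, wev$selected_features)),
      classifier_kind = wev$classifier_kind,
      classifier = rf$classifier,
      node_metrics = wev$metrics,
      is_final = FALSE
    )
    class_order <- c(class_order, winner)
    keep <- yr != winner
    Xr <- Xr[keep, , drop = FALSE]
    yr <- yr[keep]
  }

  # final direct two-class node: the lower label is scored as positive
  last <- sort(unique(yr))
  level <- level + 1L
  fev <- evaluate_candidate(Xr, yr, last[1L], config)
  fdf <- data.frame(
    level = level, candidate_class = last[1L],
    classifier_kind = fev$classifier_kind,
    accuracy = fev$metrics$accuracy, sensitivity = fev$metrics$sensitivity,
    specificity = fev$metrics$specificity, f_measure = fev$metrics$f_measure,
    mcc = fev$metrics$mcc, roc_area = fev$metrics$roc_area,
    chosen = TRUE, stringsAsFactors = FALSE
  )
  trace[[level]] <- fdf
  y01 <- make_one_vs_rest_labels(yr, last[1L])
  rf <- refit_node(Xr, y01, fev$classifier_kind, config, seed_offset = level)
  nodes[[length(nodes) + 1L]] <- list(
    target_class = last[1L], other_class = last[2L],
    selected_feature_ids = rf$selected,
    panel_feature_ids = sort(union(rf$selected, fev$selected_features)),
    classifier_kind = fev$classifier_kind,
    classifier = rf$classifier,
    node_metrics = fev$metrics,
    is_final = TRUE
  )
  class_order <- c(class_order, last[1L], last[2L])

  structure(
    list(nodes = nodes, class_order = class_order,
         feature_ids = colnames(X),
         trace = do.call(rbind, trace),
         schema_version = 1L),
    class = "hierarchy_model"
  )
}

# internal: X/y shape agreement
validate_expression_matrix_shape <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stopf("X must be a numeric matrix (samples x features)")
  if (nrow(X) != length(y)) {
    stopf("label vector length (%d) does not match the number of samples (%d)",
          length(y), nrow(X))
  }
  invisible(TRUE)
}

#' Predict classes with a fitted hierarchy
#'
#' Each sample traverses the decision points in isolation order: the first
#' node whose classifier scores it positive assigns that node's target
#' class; samples reaching the final node receive its binary decision.
#' Every sample gets exactly one class.
#'
#' @param object a `hierarchy_model`.
#' @param X samples x features matrix containing (by name) every feature
#'   any node requires, on the same scale as the training matrix.
#' @param ... unused.
#' @return vector of predicted classes, named by sample ID.
#' @export
predict.hierarchy_model <- function(object, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  for (i in seq_along(object$nodes)) {
    missing <- setdiff(object$nodes[[i]]$selected_feature_ids, colnames(X))
    if (length(missing)) {
      stopf("prediction matrix is missing feature(s) %s required by node %d (class %s)",
            paste(missing, collapse = ", "), i, object$nodes[[i]]$target_class)
    }
  }
  n <- nrow(X)
  out <- rep(NA, n)
  active <- rep(TRUE, n)
  for (node in object$nodes) {
    if (!any(active)) break
    sc <- predict_node_score(node$classifier, X[active, , drop = FALSE])
    pos <- sc > 0
    idx <- which(active)
    if (node$is_final) {
      out[idx[pos]] <- node$target_class
      out[idx[!pos]] <- node$other_class
      active[idx] <- FALSE
    } else {
      out[idx[pos]] <- node$target_class
      active[idx[pos]] <- FALSE
    }
  }
  names(out) <- rownames(X)
  out
}

#' Export the hierarchy build trace
#'
#' One row per candidate class per level with the six metrics, the
#' retained classifier kind and the chosen flag.
#'
#' @param model a `hierarchy_model`.
#' @param path output TSV path.
#' @export
write_build_trace <- function(model, path) {
  stopifnot(inherits(model, "hierarchy_model"))
  utils::write.table(model$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.hierarchy_model <- function(x, ...) {
  cat(sprintf("Hierarchical one-vs-rest model: %d decision points, class order %s\n",
              length(x$nodes), paste(x$class_order, collapse = " > ")))
  for (i in seq_along(x$nodes)) {
    nd <- x$nodes[[i]]
    cat(sprintf("  node %d: %s (%s, %d features, CV accuracy %.1f%%)\n",
                i,
                if (nd$is_final) sprintf("%s vs %s", nd$target_class, nd$other_class)
                else sprintf("%s vs rest", nd$target_class),
                nd$classifier_kind, length(nd$selected_feature_ids),
                nd$node_metrics$accuracy))
  }
  invisible(x)
}
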