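# JSON serialization of fitted hierarchy models. The on-disk document has
# an explicit schema_version; classifier parameters are plain numeric
# arrays, so a reloaded model reproduces the in-memory predictions exactly.

.hierovr_schema_version <- 1L

#' Serialize a hierarchy model to JSON
#'
#' @param model a `hierarchy_model`.
#' @param path output path.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "hierarchy_model"))
  doc <- list(
    format = "hierovr-model",
    schema_version = .hierovr_schema_version,
    class_order = model$class_order,
    feature_ids = model$feature_ids,
    nodes = lapply(model$nodes, function(nd) list(
      target_class = nd$target_class,
      other_class = nd$other_class,
      is_final = nd$is_final,
      classifier_kind = nd$classifier_kind,
      selected_feature_ids = as.list(nd$selected_feature_ids),
      panel_feature_ids = as.list(nd$panel_feature_ids %||% nd$selected_feature_ids),
      node_metrics = nd$node_metrics[c("accuracy", "sensitivity", "specificity",
                                       "f_measure", "mcc", "roc_area")],
      classifier = list(
        kind = nd$classifier$kind,
        features = as.list(nd$classifier$features),
        params = nd$classifier$params
      )
    )),
    trace = model$trace
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized hierarchy model
#'
#' Rejects documents whose schema version does not match the one this
#' package writes.
#'
#' @param path path to a JSON file written by [serialize_model()].
#' @return a `hierarchy_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stopf("corrupted model file %s: %s", path, conditionMessage(e)))
  if (!identical(doc$format, "hierovr-model")) {
    stopf("%s is not a hierovr model file", path)
  }
  if (!identical(as.integer(doc$schema_version), .hierovr_schema_version)) {
    stopf("model schema version %s does not match supported version %d",
          doc$schema_version, .hierovr_schema_version)
  }
  nodes <- lapply(doc$nodes, function(nd) {
    params <- nd$classifier$params
    if (nd$classifier$kind == "gaussian-nb") {
      params <- list(
        prior = as.numeric(unlist(params$prior)),
        mean = do.call(rbind, lapply(params$mean, function(r) as.numeric(unlist(r)))),
        var = do.call(rbind, lapply(params$var, function(r) as.numeric(unlist(r))))
      )
    } else {
      params <- list(w = as.numeric(unlist(params$w)), b = as.numeric(params$b))
    }
    metrics <- lapply(nd$node_metrics, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
    class(metrics) <- "node_metrics"
    list(
      target_class = simplify_class(nd$target_class),
      other_class = if (is.null(nd$other_class)) NA else simplify_class(nd$other_class),
      selected_feature_ids = as.character(unlist(nd$selected_feature_ids)),
      panel_feature_ids = as.character(unlist(nd$panel_feature_ids)),
      classifier_kind = nd$classifier_kind,
      classifier = structure(
        list(kind = nd$classifier$kind,
             features = as.character(unlist(nd$classifier$features)),
             params = params),
        class = "node_classifier"
      ),
      node_metrics = metrics,
      is_final = isTRUE(nd$is_final)
    )
  })
  model <- structure(
    list(
      nodes = nodes,
      class_order = simplify_class(doc$class_order),
      feature_ids = as.character(unlist(doc$feature_ids)),
      trace = if (is.null(doc$trace)) NULL else
        as.data.frame(do.call(rbind, lapply(doc$trace, function(r)
          lapply(r, function(v) if (is.null(v)) NA else v)))),
      schema_version = as.integer(doc$schema_version)
    ),
    class = "hierarchy_model"
  )
  validate_hierarchy_model(model)
  model
}

# JSON round-trips integers as integer/double and class labels may be
# numeric or character; normalise scalars without changing their meaning.
simplify_class <- function(x) {
  x <- unlist(x)
  if (is.numeric(x)) as.numeric(x) else as.character(x)
}

# Structural invariants every (de)serialized model must satisfy.
validate_hierarchy_model <- function(model) {
  n_classes <- length(model$class_order)
  if (length(model$nodes) != n_classes - 1L) {
    stopf("model has %d decision points but %d classes (expected %d)",
          length(model$nodes), n_classes, n_classes - 1L)
  }
  if (anyDuplicated(model$class_order)) stopf("class_order contains duplicates")
  feats <- unique(unlist(lapply(model$nodes, `[[`, "selected_feature_ids")))
  unknown <- setdiff(feats, model$feature_ids)
  if (length(unknown)) {
    stopf("node feature(s) absent from the training feature set: %s",
          paste(unknown, collapse = ", "))
  }
  invisible(model)
}
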