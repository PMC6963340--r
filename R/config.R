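# Merged run configuration for the command-line entry points. Every module
# default is overridable from a YAML file; unknown keys are rejected so
# typos never silently fall back to defaults.

#' Default run configuration
#'
#' The full, nested configuration consumed by the command-line entry
#' points, with every module default spelled out.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    log_level = "info",
    data = list(
      orientation = "features_by_samples",
      log2_transform = TRUE,
      sep = "\t"
    ),
    resampling = list(
      smote_k = 5L, ncl_k = 3L, target_ratio = 1.0, ncl_scope = "majority_only"
    ),
    selection = list(
      method = "equal_frequency", n_bins = 10L, top_k = 100L,
      max_features = 15L, min_delta = 0, inner_folds = 5L,
      include_diagonal = TRUE, classifier = "linear-svm"
    ),
    hierarchy = list(
      cv_folds = 10L,
      classifier_kinds = c("gaussian-nb", "linear-svm"),
      min_class_size = 4L
    ),
    simulate = list(
      class_sizes = c(10L, 55L, 24L, 10L, 4L), n_features = 2000L,
      markers_per_class = 3L, effect_size = 2.0,
      base_log_mean = 3.0, base_log_sd = 1.5, within_class_sd = 0.5,
      dropout_rate = 0.1
    )
  ), class = "run_config")
}

# Recursively merge user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s)%s: %s",
          if (nzchar(path)) sprintf(" under '%s'", path) else "",
          paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  path = if (nzchar(path)) paste(path, k, sep = ".") else k)
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()]; unknown
#' keys raise an error naming the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  structure(merge_config(unclass(cfg), user), class = "run_config")
}

# Materialise module configs from a run_config.
config_objects <- function(cfg) {
  sel <- cfg$selection
  list(
    resampling = resampling_config(
      smote_k = cfg$resampling$smote_k, ncl_k = cfg$resampling$ncl_k,
      target_ratio = cfg$resampling$target_ratio,
      ncl_scope = cfg$resampling$ncl_scope, seed = cfg$seed
    ),
    selection = selection_config(
      scheme = discretization_scheme(sel$method, sel$n_bins),
      top_k = sel$top_k, max_features = sel$max_features,
      min_delta = sel$min_delta, inner_folds = sel$inner_folds,
      include_diagonal = sel$include_diagonal, classifier = sel$classifier
    ),
    simulation = simulation_config(
      class_sizes = cfg$simulate$class_sizes, n_features = cfg$simulate$n_features,
      markers_per_class = cfg$simulate$markers_per_class,
      effect_size = cfg$simulate$effect_size,
      base_log_mean = cfg$simulate$base_log_mean,
      base_log_sd = cfg$simulate$base_log_sd,
      within_class_sd = cfg$simulate$within_class_sd,
      dropout_rate = cfg$simulate$dropout_rate, seed = cfg$seed
    )
  )
}

# Hierarchy config assembled from a run_config.
hierarchy_config_from_run <- function(cfg) {
  obj <- config_objects(cfg)
  hierarchy_config(
    cv_folds = cfg$hierarchy$cv_folds,
    classifier_kinds = cfg$hierarchy$classifier_kinds,
    resampling = obj$resampling, selection = obj$selection,
    min_class_size = cfg$hierarchy$min_class_size, seed = cfg$seed
  )
}
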