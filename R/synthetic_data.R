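# Synthetic TPM-matrix generator with planted class-specific markers.
#
# The generator emulates the structure of the study data the method targets:
# a heavily imbalanced five-group cohort (10/55/24/10/4 samples), ~10^3-10^4
# transcript features with log-normal TPM background, a small disjoint set
# of marker transcripts per class whose log2 expression is shifted upward in
# that class, and independent dropout zeros. Log-normal background (rather
# than negative-binomial counts) is used because the pipeline consumes
# already-normalised TPM, not raw counts.
#
# The background is hierarchical, as in real expression matrices: each
# transcript has its own baseline log2-TPM mean drawn from the
# transcriptome-wide distribution N(base_log_mean, base_log_sd), and
# samples vary around that baseline with a (much smaller) within-class
# biological sd. Collapsing the two scales into one would make every
# transcript's sample-to-sample noise as wide as the whole transcriptome
# spread, which no TPM matrix exhibits and which would drown the planted
# markers.

#' Simulation configuration
#'
#' Defaults are the study conditions the package is tested under: the
#' five-group class imbalance 10/55/24/10/4, 2000 transcript features
#' (scalable toward the ~42,000 of a full transcriptome), 3 planted markers
#' per class with a +2 log2-fold shift, background log2-TPM ~
#' Normal(3, 1.5), and 10% dropout.
#'
#' @param class_sizes per-class sample counts (>= 2 classes).
#' @param n_features total number of features.
#' @param markers_per_class planted markers per class (disjoint across
#'   classes).
#' @param effect_size mean log2 shift of a marker within its own class.
#' @param base_log_mean,base_log_sd mean and sd of the transcriptome-wide
#'   distribution of per-transcript baseline log2-TPM means.
#' @param within_class_sd sample-to-sample (within-class) sd of a
#'   transcript's log2 expression around its baseline (default 0.5,
#'   typical bulk RNA-seq biological variability; with dropout, a single
#'   +2.0 marker is individually informative but insufficient, so a panel
#'   is needed for reliable classification).
#' @param dropout_rate probability any value is zeroed, in [0, 1).
#' @param seed RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(class_sizes = c(10L, 55L, 24L, 10L, 4L),
                              n_features = 2000L,
                              markers_per_class = 3L,
                              effect_size = 2.0,
                              base_log_mean = 3.0,
                              base_log_sd = 1.5,
                              within_class_sd = 0.5,
                              dropout_rate = 0.1,
                              seed = 1L) {
  if (length(class_sizes) < 2L) stopf("at least 2 classes are required")
  stopifnot(all(class_sizes >= 1L), n_features >= 1L, markers_per_class >= 1L,
            effect_size >= 0, base_log_sd > 0, within_class_sd > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (length(class_sizes) * markers_per_class > n_features) {
    stopf("not enough features to plant %d disjoint markers for %d classes",
          markers_per_class, length(class_sizes))
  }
  structure(
    list(class_sizes = as.integer(class_sizes), n_features = as.integer(n_features),
         markers_per_class = as.integer(markers_per_class),
         effect_size = effect_size, base_log_mean = base_log_mean,
         base_log_sd = base_log_sd, within_class_sd = within_class_sd,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a TPM expression dataset with planted markers
#'
#' Each transcript gets a baseline log2-TPM mean drawn from
#' `Normal(base_log_mean, base_log_sd)`; sample values vary around the
#' baseline with sd `within_class_sd`; marker features additionally have
#' `effect_size` added to their mean within their own class; dropout then
#' zeroes each value independently. Deterministic under the config seed.
#' Gleason-style score strings are attached so label files written from a
#' simulation round-trip through the score parser (groups beyond the fifth
#' fall back to plain group labels).
#'
#' @param config a [simulation_config()].
#' @param reference optional `simulated_dataset` from a previous call with
#'   a compatible configuration; its planted markers and per-transcript
#'   baselines are reused, which is how matched held-out test sets are
#'   generated.
#' @return list of class `simulated_dataset`: `matrix` (samples x features
#'   TPM), `labels` (data.frame `sample_id`, `score`, `group`), `truth`
#'   (data.frame `group`, `feature_id`, `effect_size`), `baseline`
#'   (per-transcript baseline log2 means).
#' @export
simulate_expression <- function(config = simulation_config(), reference = NULL) {
  C <- length(config$class_sizes)
  n <- sum(config$class_sizes)
  p <- config$n_features
  feature_ids <- sprintf("TX%05d", seq_len(p))
  sample_ids <- sprintf("S%03d", seq_len(n))
  groups <- rep(seq_len(C), times = config$class_sizes)

  score_for_group <- c("6", "3+4=7", "4+3=7", "8", "9")
  scores <- if (C <= 5L) score_for_group[groups] else as.character(groups)

  with_seed(config$seed, {
    if (is.null(reference)) {
      marker_idx <- sample.int(p, C * config$markers_per_class)
      truth <- data.frame(
        group = rep(seq_len(C), each = config$markers_per_class),
        feature_id = feature_ids[marker_idx],
        effect_size = config$effect_size,
        stringsAsFactors = FALSE
      )
      baseline <- stats::rnorm(p, config$base_log_mean, config$base_log_sd)
      names(baseline) <- feature_ids
    } else {
      stopifnot(inherits(reference, "simulated_dataset"))
      truth <- reference$truth
      baseline <- reference$baseline
      if (!all(truth$feature_id %in% feature_ids) || length(baseline) != p) {
        stopf("reference dataset is incompatible with this configuration")
      }
    }
    logm <- matrix(stats::rnorm(n * p, 0, config$within_class_sd),
                   n, p, dimnames = list(sample_ids, feature_ids))
    logm <- sweep(logm, 2L, baseline, "+")
    for (r in seq_len(nrow(truth))) {
      cls <- truth$group[r]
      j <- match(truth$feature_id[r], feature_ids)
      rows <- which(groups == cls)
      logm[rows, j] <- logm[rows, j] + truth$effect_size[r]
    }
    tpm <- 2^logm
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * p) < config$dropout_rate, n, p)
      tpm[drop] <- 0
    }
    labels <- data.frame(sample_id = sample_ids, score = scores,
                         group = as.integer(groups), stringsAsFactors = FALSE)
    structure(list(matrix = tpm, labels = labels, truth = truth,
                   baseline = baseline),
              class = "simulated_dataset")
  })
}

#' Write a simulated dataset to disk
#'
#' Produces `<prefix>matrix.tsv` (features x samples TPM),
#' `<prefix>labels.tsv` (sample_id, score) and `<prefix>truth.tsv`, so
#' downstream runs and tests never reach into generator internals.
#'
#' @param sim a `simulated_dataset`.
#' @param prefix output path prefix (directory part must exist).
#' @return invisible character vector of the three paths.
#' @export
write_simulated_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "simulated_dataset"))
  paths <- paste0(prefix, c("matrix.tsv", "labels.tsv", "truth.tsv"))
  write_expression_matrix(sim$matrix, paths[1L], orientation = "features_by_samples")
  utils::write.table(sim$labels[, c("sample_id", "score")], paths[2L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Marker-recovery report
#'
#' Per-class precision and recall of selected features against the planted
#' truth: precision = |selected n truth| / |selected|, recall =
#' |selected n truth| / |truth|.
#'
#' @param selected_per_class named list: class -> character vector of
#'   selected feature IDs.
#' @param truth `truth` data.frame of a `simulated_dataset`.
#' @param feature_ids optional full feature namespace for ID validation.
#' @return data.frame with columns `group`, `n_selected`, `n_truth`,
#'   `precision`, `recall`.
#' @export
truth_recovery_report <- function(selected_per_class, truth, feature_ids = NULL) {
  if (!is.null(feature_ids)) {
    unknown <- setdiff(unique(c(unlist(selected_per_class), truth$feature_id)),
                       feature_ids)
    if (length(unknown)) {
      stopf("unknown feature ID(s): %s", paste(unknown, collapse = ", "))
    }
  }
  out <- lapply(names(selected_per_class), function(cl) {
    sel <- unique(selected_per_class[[cl]])
    tr <- truth$feature_id[truth$group == as.integer(cl)]
    hit <- length(intersect(sel, tr))
    data.frame(
      group = as.integer(cl), n_selected = length(sel), n_truth = length(tr),
      precision = if (length(sel)) hit / length(sel) else 0,
      recall = if (length(tr)) hit / length(tr) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
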