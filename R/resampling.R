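# Class-imbalance correction for a binary one-vs-rest training set:
# neighbourhood cleaning rule (NCL) undersampling followed by SMOTE
# oversampling of the minority class. Cleaning runs first so that synthetic
# points are never interpolated toward noisy rows that NCL would remove.

#' Resampling configuration
#'
#' @param smote_k number of minority-class nearest neighbours SMOTE may
#'   interpolate toward (default 5; capped at the minority size minus one).
#' @param ncl_k neighbour count for the neighbourhood cleaning rule. The
#'   rule as used here removes a sample when at least two of its three
#'   nearest neighbours carry a different class, so `ncl_k` is 3 unless
#'   explicitly overridden.
#' @param target_ratio desired minority/majority size ratio after
#'   resampling, in (0, 1]; default 1 (full balance).
#' @param ncl_scope `"majority_only"` (default) restricts removal to
#'   majority-class rows, matching the rule's role of undersampling the
#'   majority class; `"any_class"` applies the cleaning vote to every row.
#'   The default matters in high dimensions, where nearest-neighbour votes
#'   are noise-dominated and an unrestricted vote systematically strips
#'   the minority class.
#' @param seed RNG seed for the SMOTE interpolation draws.
#' @return a list of class `resampling_config`.
#' @export
resampling_config <- function(smote_k = 5L, ncl_k = 3L, target_ratio = 1.0,
                              ncl_scope = c("majority_only", "any_class"),
                              seed = 1L) {
  ncl_scope <- match.arg(ncl_scope)
  stopifnot(smote_k >= 1L, ncl_k >= 1L,
            target_ratio > 0, target_ratio <= 1)
  structure(
    list(smote_k = as.integer(smote_k), ncl_k = as.integer(ncl_k),
         target_ratio = target_ratio, ncl_scope = ncl_scope,
         seed = as.integer(seed)),
    class = "resampling_config"
  )
}

#' Neighbourhood cleaning rule undersampling
#'
#' A row is dropped when at least two of its `ncl_k` (= 3) nearest
#' neighbours, by Euclidean distance in feature space and excluding the row
#' itself, belong to a different class. With
#' `ncl_scope = "majority_only"`, only majority-class rows are eligible for
#' removal. Neighbour ties are broken by lowest row index.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary label vector aligned with `X` rows.
#' @param config a [resampling_config()].
#' @return integer vector of retained row indices.
#' @export
ncl_undersample <- function(X, y, config = resampling_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < config$ncl_k + 1L) {
    warnf("NCL skipped: %d rows is fewer than ncl_k + 1 = %d; input returned unchanged",
          n, config$ncl_k + 1L)
    return(seq_len(n))
  }
  dmat <- as.matrix(stats::dist(X))
  majority <- names(which.max(table(y)))
  vote_threshold <- ceiling((config$ncl_k + 1L) / 2L)  # 2 of 3
  drop <- vapply(seq_len(n), function(i) {
    nn <- knn_indices(dmat, i, config$ncl_k)
    disagree <- sum(y[nn] != y[i])
    eligible <- config$ncl_scope == "any_class" || as.character(y[i]) == majority
    eligible && disagree >= vote_threshold
  }, logical(1L))
  which(!drop)
}

#' SMOTE oversampling of a minority class
#'
#' Each synthetic sample is drawn on the segment joining a minority row
#' `a` to one of its `smote_k` nearest minority neighbours `b`:
#' `s = a + u * (b - a)` with `u ~ Uniform(0, 1)`. Base rows are cycled in
#' order so synthetic coverage is spread over the whole minority class; the
#' neighbour and `u` come from the seeded RNG.
#'
#' @param X_minority numeric matrix of minority-class rows (at least 2).
#' @param n_synthetic number of synthetic rows to generate (may be 0).
#' @param config a [resampling_config()]; uses `smote_k` and `seed`.
#' @return a list with `X` (the `n_synthetic` x p synthetic matrix) and
#'   `parents` (data.frame with the base row `a`, neighbour `b`, and `u`
#'   used for each synthetic row).
#' @export
smote_oversample <- function(X_minority, n_synthetic,
                             config = resampling_config()) {
  X_minority <- as.matrix(X_minority)
  n <- nrow(X_minority)
  p <- ncol(X_minority)
  if (n_synthetic < 0) stopf("n_synthetic must be >= 0")
  if (n_synthetic == 0L) {
    return(list(X = matrix(numeric(0), 0L, p, dimnames = list(NULL, colnames(X_minority))),
                parents = data.frame(a = integer(0), b = integer(0), u = numeric(0))))
  }
  if (n < 2L) stopf("SMOTE requires at least 2 minority rows to form an interpolation segment")
  k <- min(config$smote_k, n - 1L)
  dmat <- as.matrix(stats::dist(X_minority))
  nn <- lapply(seq_len(n), function(i) knn_indices(dmat, i, k))
  with_seed(config$seed, {
    a_idx <- ((seq_len(n_synthetic) - 1L) %% n) + 1L
    b_idx <- vapply(a_idx, function(i) nn[[i]][sample.int(k, 1L)], integer(1L))
    u <- stats::runif(n_synthetic)
    S <- X_minority[a_idx, , drop = FALSE] +
      u * (X_minority[b_idx, , drop = FALSE] - X_minority[a_idx, , drop = FALSE])
    rownames(S) <- sprintf("synth_%04d", seq_len(n_synthetic))
    list(X = S, parents = data.frame(a = a_idx, b = b_idx, u = u))
  })
}

#' Rebalance a binary training set (NCL then SMOTE)
#'
#' Applies the neighbourhood cleaning rule, then SMOTE-oversamples the
#' minority class until minority/majority reaches `target_ratio`. If the
#' cleaning step would remove an entire class, cleaning is rolled back for
#' that class with a warning. Original rows are never modified; every
#' output row carries a provenance tag.
#'
#' @param X numeric feature matrix (rows = samples; rownames kept).
#' @param y binary label vector (both classes present).
#' @param config a [resampling_config()].
#' @return a list of class `resampled_set` with elements `X`, `y`,
#'   `provenance` (data.frame: `row_id`, `origin` in
#'   `{original, synthetic}`, `parent_a`, `parent_b`, `u`) and
#'   `removed` (row ids dropped by NCL).
#' @export
rebalance <- function(X, y, config = resampling_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  classes <- sort(unique(as.vector(y)))
  if (length(classes) != 2L) stopf("rebalance() requires a binary label vector with both classes present")
  if (is.null(rownames(X))) rownames(X) <- sprintf("row_%04d", seq_len(n))

  keep <- ncl_undersample(X, y, config)
  # roll back cleaning for any class it (nearly) wiped out: below two rows
  # a class can no longer anchor SMOTE interpolation segments
  for (cl in classes) {
    n_before <- sum(y == cl)
    if (sum(y[keep] == cl) < min(2L, n_before)) {
      warnf("NCL left class %s with fewer than 2 samples; cleaning rolled back for that class", cl)
      keep <- sort(union(keep, which(y == cl)))
    }
  }
  removed_ids <- rownames(X)[setdiff(seq_len(n), keep)]
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]

  counts <- table(yk)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)[1L]
  n_min <- as.integer(counts[minority])
  n_maj <- as.integer(counts[majority])
  n_synth <- max(0L, as.integer(ceiling(config$target_ratio * n_maj)) - n_min)
  if (n_min < 2L && n_synth > 0L) {
    warnf("minority class has a single sample after cleaning; SMOTE skipped")
    n_synth <- 0L
  }

  min_rows <- which(yk == minority)
  sm <- smote_oversample(Xk[min_rows, , drop = FALSE], n_synth, config)

  prov_orig <- data.frame(
    row_id = rownames(Xk), origin = "original",
    parent_a = NA_character_, parent_b = NA_character_, u = NA_real_,
    stringsAsFactors = FALSE
  )
  min_ids <- rownames(Xk)[min_rows]
  prov_syn <- if (n_synth > 0L) data.frame(
    row_id = rownames(sm$X), origin = "synthetic",
    parent_a = min_ids[sm$parents$a], parent_b = min_ids[sm$parents$b],
    u = sm$parents$u, stringsAsFactors = FALSE
  ) else prov_orig[0L, ]

  y_out <- c(yk, rep(yk[min_rows[1L]], n_synth))  # preserves the label type
  structure(
    list(
      X = rbind(Xk, sm$X),
      y = y_out,
      provenance = rbind(prov_orig, prov_syn),
      removed = removed_ids
    ),
    class = "resampled_set"
  )
}

#' Export a resampling provenance table
#'
#' Writes the per-row audit trail of [rebalance()] as TSV
#' (`row_id`, `origin`, `parent_a`, `parent_b`, `u`).
#'
#' @param rs a `resampled_set`.
#' @param path output path.
#' @export
write_provenance <- function(rs, path) {
  stopifnot(inherits(rs, "resampled_set"))
  utils::write.table(rs$provenance, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
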