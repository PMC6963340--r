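# Two-stage hybrid feature selection for one binary one-vs-rest problem:
# an information-gain filter over all features, then a greedy
# minimum-redundancy maximum-relevance (mRMR) wrapper that only keeps a
# candidate feature if it improves the cross-validated accuracy of a
# linear-kernel SVM.
#
# All entropies are Shannon entropies in bits. Continuous expression values
# are discretised (equal-frequency by default) before any entropy is taken;
# bin edges are learned on training data only.

#' Shannon entropy of a discrete vector, in bits
#'
#' `H(A) = -sum_a p(a) log2 p(a)`, with `0 * log2(0)` defined as 0.
#'
#' @param labels non-empty discrete vector.
#' @return entropy in bits.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stopf("entropy() of an empty vector is undefined")
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(A | X) in bits
#'
#' `H(A|X) = sum_x p(x) H(A | X = x)`; bins with zero mass contribute
#' nothing.
#'
#' @param labels discrete class vector.
#' @param feature_bins discrete conditioning vector, same length.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(labels, feature_bins) {
  if (length(labels) != length(feature_bins)) {
    stopf("conditional_entropy(): length mismatch (%d labels vs %d bins)",
          length(labels), length(feature_bins))
  }
  n <- length(labels)
  joint <- table(feature_bins, labels)
  px <- rowSums(joint) / n
  h <- 0
  for (r in seq_len(nrow(joint))) {
    if (px[r] == 0) next
    pax <- joint[r, ] / sum(joint[r, ])
    pax <- pax[pax > 0]
    h <- h + px[[r]] * (-sum(pax * log2(pax)))
  }
  unname(h)
}

#' Mutual information between two discrete vectors, in bits
#'
#' `I(U;V) = H(U) + H(V) - H(U,V)`; symmetric and non-negative.
#'
#' @param u_bins,v_bins equal-length discrete vectors.
#' @return mutual information in bits.
#' @export
mutual_information <- function(u_bins, v_bins) {
  if (length(u_bins) != length(v_bins)) {
    stopf("mutual_information(): length mismatch (%d vs %d)",
          length(u_bins), length(v_bins))
  }
  entropy(u_bins) + entropy(v_bins) -
    entropy(paste(u_bins, v_bins, sep = "\r"))
}

# Fast contingency-table versions of the entropy operations above, used in
# the inner loops (same math, tabulate() instead of table()). Inputs are
# integer codes starting at 1.
fast_entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

fast_ig <- function(y_codes, n_y, bins, n_b, h_class) {
  n <- length(y_codes)
  cm <- matrix(tabulate(bins + n_b * (y_codes - 1L), nbins = n_b * n_y), n_b, n_y)
  rs <- rowSums(cm)
  hax <- 0
  for (r in which(rs > 0)) {
    p <- cm[r, ]
    p <- p[p > 0] / rs[r]
    hax <- hax + (rs[r] / n) * (-sum(p * log2(p)))
  }
  max(h_class - hax, 0)
}

fast_mi <- function(u, n_u, v, n_v) {
  n <- length(u)
  hu <- fast_entropy_counts(tabulate(u, nbins = n_u), n)
  hv <- fast_entropy_counts(tabulate(v, nbins = n_v), n)
  huv <- fast_entropy_counts(tabulate(u + n_u * (v - 1L), nbins = n_u * n_v), n)
  max(hu + hv - huv, 0)
}

#' Discretization scheme for continuous features
#'
#' @param method `"equal_frequency"` (quantile bins; default, robust to the
#'   heavy right skew of TPM) or `"equal_width"`.
#' @param n_bins number of bins (default 10; at least 2).
#' @return list of class `discretization_scheme`.
#' @export
discretization_scheme <- function(method = c("equal_frequency", "equal_width"),
                                  n_bins = 10L) {
  method <- match.arg(method)
  stopifnot(n_bins >= 2L)
  structure(list(method = method, n_bins = as.integer(n_bins)),
            class = "discretization_scheme")
}

# Learn interior bin edges for one feature on training values.
# Returns a strictly increasing numeric vector (possibly empty, when the
# feature is constant or near-constant: everything falls in one bin).
fit_bin_edges <- function(x, scheme) {
  if (scheme$method == "equal_frequency") {
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = scheme$n_bins + 1L),
                          names = FALSE, type = 7)
    edges <- unique(qs[-c(1L, length(qs))])
  } else {
    r <- range(x)
    if (r[1L] == r[2L]) return(numeric(0))
    edges <- seq(r[1L], r[2L], length.out = scheme$n_bins + 1L)[-c(1L, scheme$n_bins + 1L)]
  }
  unique(edges[is.finite(edges)])
}

# Assign values to bins given interior edges; held-out values beyond the
# training range fall into the outermost bins.
apply_bin_edges <- function(x, edges) {
  if (length(edges) == 0L) return(rep.int(1L, length(x)))
  findInterval(x, edges, left.open = TRUE) + 1L
}

# Discretise every column of X with edges learned from X itself.
discretize_matrix <- function(X, scheme) {
  B <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    B[, j] <- apply_bin_edges(X[, j], fit_bin_edges(X[, j], scheme))
  }
  B
}

#' Information gain of a continuous feature about a class vector
#'
#' `IG(A, X) = H(A) - H(A | bin(X))`, with the feature discretised by the
#' supplied scheme (edges learned from `feature_values` themselves).
#'
#' @param labels discrete class vector.
#' @param feature_values continuous feature vector, same length.
#' @param scheme a [discretization_scheme()].
#' @return information gain in bits (never negative beyond rounding).
#' @export
information_gain <- function(labels, feature_values,
                             scheme = discretization_scheme()) {
  if (length(labels) != length(feature_values)) {
    stopf("information_gain(): length mismatch")
  }
  bins <- apply_bin_edges(feature_values, fit_bin_edges(feature_values, scheme))
  ig <- entropy(labels) - conditional_entropy(labels, bins)
  max(ig, 0)
}

#' Rank all features by information gain
#'
#' Scores every column of `X` by [information_gain()] and returns the top
#' `top_k` features in descending score order; ties are broken by
#' lexicographic feature ID so the ranking is reproducible.
#'
#' @param X samples x features numeric matrix.
#' @param y class vector (one per row of `X`).
#' @param scheme a [discretization_scheme()].
#' @param top_k number of features to retain (default 100).
#' @return list of class `ig_ranking` with `feature_ids`, `scores` (bits,
#'   aligned with `feature_ids`), and `h_class` (class entropy, bits).
#' @export
rank_by_ig <- function(X, y, scheme = discretization_scheme(), top_k = 100L) {
  stopifnot(top_k >= 1L)
  p <- ncol(X)
  if (top_k > p) {
    warnf("top_k = %d exceeds the %d available features; returning the full ranking", top_k, p)
    top_k <- p
  }
  h_class <- entropy(y)
  y_codes <- as.integer(factor(y))
  n_y <- max(y_codes)
  scores <- vapply(seq_len(p), function(j) {
    bins <- apply_bin_edges(X[, j], fit_bin_edges(X[, j], scheme))
    fast_ig(y_codes, n_y, bins, max(bins), h_class)
  }, numeric(1L))
  ids <- colnames(X) %||% sprintf("f%05d", seq_len(p))
  ord <- order(-scores, ids)
  sel <- ord[seq_len(top_k)]
  structure(
    list(feature_ids = ids[sel], scores = unname(scores[sel]), h_class = h_class),
    class = "ig_ranking"
  )
}

#' Selection configuration for the hybrid filter + wrapper stage
#'
#' @param scheme discretization scheme shared by the information-gain filter
#'   and all mutual-information terms of the mRMR objective.
#' @param top_k size of the information-gain filter shortlist handed to the
#'   wrapper (default 100).
#' @param max_features hard cap on the selected subset size (default 15).
#' @param min_delta minimum cross-validated accuracy improvement required to
#'   keep a tentatively added feature (default 0: strict improvement).
#' @param inner_folds stratified folds for the wrapper's internal accuracy
#'   estimate (default 5).
#' @param include_diagonal include the `i = j` self-information terms in the
#'   redundancy double sum (default `TRUE`, the double sum read as written;
#'   `FALSE` gives the common mRMR practice of off-diagonal-only redundancy).
#' @param classifier wrapped classifier kind (default `"linear-svm"`).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(scheme = discretization_scheme(),
                             top_k = 100L, max_features = 15L,
                             min_delta = 0, inner_folds = 5L,
                             include_diagonal = TRUE,
                             classifier = "linear-svm") {
  stopifnot(inherits(scheme, "discretization_scheme"),
            top_k >= 1L, max_features >= 1L, min_delta >= 0, inner_folds >= 2L)
  structure(
    list(scheme = scheme, top_k = as.integer(top_k),
         max_features = as.integer(max_features), min_delta = min_delta,
         inner_folds = as.integer(inner_folds),
         include_diagonal = isTRUE(include_diagonal), classifier = classifier),
    class = "selection_config"
  )
}

#' Create an mRMR scoring state
#'
#' Holds the binned candidate features, the class vector, the per-feature
#' class relevance `I(h, i)`, and a memoised cache of pairwise mutual
#' informations `I(i, j)`, so that redundancy terms are computed once.
#'
#' @param X_bins samples x candidates integer matrix of binned feature
#'   values (columns named by feature ID).
#' @param y class vector.
#' @param include_diagonal include `i = j` terms in the redundancy sum.
#' @return an environment of class `mrmr_state` with fields `S` (selected
#'   IDs, in selection order), `relevance`, and accessors used by
#'   [mrmr_score()].
#' @export
mrmr_state <- function(X_bins, y, include_diagonal = TRUE) {
  st <- new.env(parent = emptyenv())
  st$ids <- colnames(X_bins)
  st$X_bins <- X_bins
  st$y <- y
  st$include_diagonal <- isTRUE(include_diagonal)
  st$S <- character(0)
  st$y_codes <- as.integer(factor(y))
  st$n_y <- max(st$y_codes)
  st$n_bins <- apply(X_bins, 2L, max)
  st$relevance <- vapply(st$ids, function(f) {
    fast_mi(st$y_codes, st$n_y, X_bins[, f], st$n_bins[[f]])
  }, numeric(1L))
  st$mi_cache <- new.env(parent = emptyenv())
  class(st) <- "mrmr_state"
  st
}

# Memoised pairwise mutual information between two candidate features.
mrmr_pair_mi <- function(state, f1, f2) {
  key <- if (f1 <= f2) paste(f1, f2, sep = "\r") else paste(f2, f1, sep = "\r")
  val <- state$mi_cache[[key]]
  if (is.null(val)) {
    val <- fast_mi(state$X_bins[, f1], state$n_bins[[f1]],
                   state$X_bins[, f2], state$n_bins[[f2]])
    state$mi_cache[[key]] <- val
  }
  val
}

# Redundancy W and relevance V of a feature set, from scratch:
# W = (1/|S|^2) * sum_{i,j in S} I(i, j)   (diagonal optional)
# V = (1/|S|)   * sum_{i in S}   I(h, i)
mrmr_wv <- function(state, S) {
  m <- length(S)
  if (m == 0L) return(c(W = 0, V = 0))
  w_sum <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (!state$include_diagonal && i == j) next
      w_sum <- w_sum + mrmr_pair_mi(state, S[i], S[j])
    }
  }
  c(W = w_sum / m^2, V = sum(state$relevance[S]) / m)
}

#' mRMR score of a candidate feature
#'
#' Scores candidate `c` by `V(S u {c}) - W(S u {c})`: the mean class
#' relevance of the augmented set minus its mean pairwise redundancy, both
#' in bits. With an empty selected set this reduces to `I(h, c) - H(c)`
#' (the self-information term is the singleton's redundancy).
#'
#' @param state an [mrmr_state()].
#' @param candidate feature ID not already in the selected set.
#' @return numeric score (higher is better).
#' @export
mrmr_score <- function(state, candidate) {
  if (candidate %in% state$S) stopf("candidate %s is already selected", candidate)
  if (!candidate %in% state$ids) stopf("unknown candidate feature %s", candidate)
  wv <- mrmr_wv(state, c(state$S, candidate))
  unname(wv["V"] - wv["W"])
}

# Incremental scores for every remaining candidate at once, using
# W_sum(S u c) = W_sum(S) + 2 * sum_{s in S} I(s, c) + [diag] I(c, c).
mrmr_scores_incremental <- function(state, candidates) {
  m <- length(state$S) + 1L
  base_w <- if (length(state$S) == 0L) 0 else {
    wv <- mrmr_wv(state, state$S)
    wv[["W"]] * length(state$S)^2
  }
  base_v <- sum(state$relevance[state$S])
  vapply(candidates, function(cand) {
    cross <- if (length(state$S)) {
      sum(vapply(state$S, function(s) mrmr_pair_mi(state, s, cand), numeric(1L)))
    } else 0
    self <- if (state$include_diagonal) mrmr_pair_mi(state, cand, cand) else 0
    w <- (base_w + 2 * cross + self) / m^2
    v <- (base_v + state$relevance[[cand]]) / m
    v - w
  }, numeric(1L))
}

#' Hybrid mRMR wrapper selection
#'
#' Forward selection over the information-gain shortlist. At each step the
#' remaining candidates are ordered by [mrmr_score()]; candidates are
#' tentatively added in that order and the first whose addition improves
#' the wrapped classifier's stratified cross-validated accuracy by more
#' than `min_delta` is kept. Selection stops when no candidate improves,
#' when `max_features` is reached, or when accuracy is already perfect.
#' If no candidate beats the majority-class baseline at the first step, the
#' single highest-IG feature is returned with a warning.
#'
#' @param X samples x features numeric matrix (continuous values).
#' @param y binary label vector (0/1).
#' @param ranking an [rank_by_ig()] result; its features are the candidate
#'   shortlist.
#' @param config a [selection_config()].
#' @param seed RNG seed for the inner cross-validation folds.
#' @param provenance optional provenance data.frame (as produced by
#'   [rebalance()]) aligned with the rows of `X`. When supplied, the
#'   wrapper's inner CV folds are assigned over original rows only:
#'   synthetic rows are never used as evaluation samples, and a synthetic
#'   row joins an inner training set only if both of its parent rows lie
#'   outside that fold's evaluation set. This keeps the wrapper's accuracy
#'   estimate free of oversampling leakage.
#' @return list of class `selection_result` with `selected` (feature IDs in
#'   selection order), `accuracy` (final wrapper CV accuracy), `ranking`,
#'   and `trace` (one row per tentative addition: step, feature, V, W,
#'   mrmr score, wrapper accuracy, accepted flag).
#' @export
mrmr_wrapper_select <- function(X, y, ranking, config = selection_config(),
                                seed = 1L, provenance = NULL) {
  stopifnot(inherits(ranking, "ig_ranking"))
  cands <- ranking$feature_ids
  if (length(cands) == 0L) stopf("empty candidate ranking")
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stopf("wrapper selection requires a binary label vector")

  Xc <- X[, cands, drop = FALSE]
  n <- nrow(Xc)
  if (is.null(provenance)) {
    orig <- seq_len(n)
    parent_rows <- NULL
  } else {
    stopifnot(nrow(provenance) == n)
    orig <- which(provenance$origin == "original")
    syn <- which(provenance$origin == "synthetic")
    id2row <- stats::setNames(seq_len(n), provenance$row_id)
    parent_rows <- cbind(id2row[provenance$parent_a[syn]],
                         id2row[provenance$parent_b[syn]])
  }
  y_orig <- y[orig]
  # mutual-information statistics are computed on original rows only:
  # interpolated rows have systematically shrunken variance, which would
  # manufacture class relevance for uninformative features
  X_bins <- discretize_matrix(Xc[orig, , drop = FALSE], config$scheme)
  state <- mrmr_state(X_bins, y_orig, config$include_diagonal)
  if (length(unique(y_orig)) != 2L) stopf("wrapper selection requires both classes among original rows")
  k <- min(config$inner_folds, min(table(y_orig)))
  if (k < 2L) stopf("a class has fewer than 2 samples; wrapper CV impossible")
  folds_orig <- stratified_folds(y_orig, k, seed = derive_seed(seed, 101L))
  fold_of_row <- rep(NA_integer_, n)
  fold_of_row[orig] <- folds_orig

  cv_acc <- function(feat_ids) {
    correct <- 0L
    for (f in seq_len(k)) {
      te <- orig[folds_orig == f]
      tr <- setdiff(orig, te)
      if (!is.null(parent_rows) && length(parent_rows)) {
        safe <- !(fold_of_row[parent_rows[, 1L]] %in% f) &
                !(fold_of_row[parent_rows[, 2L]] %in% f)
        tr <- c(tr, syn[safe])
      }
      clf <- fit_node_classifier(config$classifier, Xc[tr, feat_ids, drop = FALSE], y[tr])
      pred <- predict_node_class(clf, Xc[te, feat_ids, drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    correct / length(orig)
  }

  baseline <- max(table(y_orig)) / length(y_orig)
  current <- baseline
  trace <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(cands, state$S)
    if (length(remaining) == 0L || length(state$S) >= config$max_features) break
    if (current >= 1) break  # perfect accuracy cannot strictly improve
    step <- step + 1L
    sc <- mrmr_scores_incremental(state, remaining)
    ord <- remaining[order(-sc, remaining)]
    accepted_any <- FALSE
    for (cand in ord) {
      acc <- cv_acc(c(state$S, cand))
      wv <- mrmr_wv(state, c(state$S, cand))
      accept <- acc > current + config$min_delta
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, feature_id = cand, V = wv[["V"]], W = wv[["W"]],
        mrmr_score = sc[[cand]], wrapper_accuracy = acc, accepted = accept,
        stringsAsFactors = FALSE
      )
      if (accept) {
        state$S <- c(state$S, cand)
        current <- acc
        accepted_any <- TRUE
        break
      }
    }
    if (!accepted_any) break
  }

  if (length(state$S) == 0L) {
    warnf("no candidate improved on the %.3f majority baseline; falling back to the top information-gain feature", baseline)
    state$S <- cands[1L]
    current <- cv_acc(state$S)
  }
  structure(
    list(selected = state$S, accuracy = current, ranking = ranking,
         trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(step = integer(0), feature_id = character(0), V = numeric(0),
                      W = numeric(0), mrmr_score = numeric(0),
                      wrapper_accuracy = numeric(0), accepted = logical(0))),
    class = "selection_result"
  )
}

#' Run the full hybrid selection stage (filter, then wrapper)
#'
#' @inheritParams mrmr_wrapper_select
#' @return a `selection_result` (see [mrmr_wrapper_select()]).
#' @export
select_features <- function(X, y, config = selection_config(), seed = 1L,
                            provenance = NULL) {
  if (is.null(provenance)) {
    ranking <- rank_by_ig(X, y, config$scheme, config$top_k)
  } else {
    # rank on original rows only (see mrmr_wrapper_select)
    orig <- which(provenance$origin == "original")
    ranking <- rank_by_ig(X[orig, , drop = FALSE], y[orig],
                          config$scheme, config$top_k)
  }
  mrmr_wrapper_select(X, y, ranking, config, seed = seed,
                      provenance = provenance)
}
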