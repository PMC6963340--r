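# Shared fixtures: everything is generated in code at test time.

log_tpm <- function(m) log2(m + 1)

# A small five-class simulation that keeps unit tests fast while preserving
# the structure of the default study conditions (imbalance incl. a 4-sample
# class, planted markers, dropout).
small_sim_config <- function(seed = 1L, ...) {
  args <- list(class_sizes = c(8L, 16L, 10L, 6L, 4L), n_features = 120L,
               seed = seed)
  utils::modifyList(args, list(...)) |>
    do.call(what = simulation_config)
}

# Fast hierarchy configuration for small fixtures.
small_hier_config <- function(seed = 1L, ...) {
  args <- list(
    cv_folds = 3L,
    selection = selection_config(top_k = 25L, max_features = 6L),
    seed = seed
  )
  utils::modifyList(args, list(...)) |>
    do.call(what = hierarchy_config)
}

# A cleanly separable two-class dataset (huge effect, no dropout): used
# where an example expects perfect classification.
separable_sim <- function(seed = 1L, classes = 2L) {
  sizes <- c(12L, 12L, 10L, 8L, 6L)[seq_len(classes)]
  simulate_expression(simulation_config(
    class_sizes = sizes, n_features = 60L, markers_per_class = 3L,
    effect_size = 6, within_class_sd = 0.3, dropout_rate = 0, seed = seed
  ))
}

# Brute-force Shannon entropy of a discrete vector (independent oracle).
oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_conditional_entropy <- function(a, x) {
  h <- 0
  for (xv in unique(x)) {
    idx <- x == xv
    h <- h + mean(idx) * oracle_entropy(a[idx])
  }
  h
}

oracle_mutual_information <- function(u, v) {
  oracle_entropy(u) + oracle_entropy(v) -
    oracle_entropy(paste(u, v, sep = "|"))
}

# Brute-force NCL: all-pairs Euclidean distances, 2-of-3 neighbour vote,
# ties broken by lowest row index (independent of the implementation).
oracle_ncl <- function(X, y, scope = "majority_only", k = 3L) {
  n <- nrow(X)
  majority <- names(which.max(table(y)))
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    nn <- order(d)[seq_len(k)]
    disagree <- sum(y[nn] != y[i])
    eligible <- scope == "any_class" || as.character(y[i]) == majority
    keep[i] <- !(eligible && disagree >= 2L)
  }
  which(keep)
}
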