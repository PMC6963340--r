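# Internal helpers shared across modules.

#' Derive a module-level seed from a global seed
#'
#' A single user-facing seed fans out to per-stage seeds through a fixed
#' affine map, so that reordering pipeline stages never silently changes the
#' random stream another stage sees. Results stay within the 32-bit integer
#' range R requires of `set.seed()`.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (each call site uses a distinct one).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# stop() with sprintf formatting and no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic k nearest neighbours of row i in a distance matrix,
# excluding self; ties broken by lowest row index (order() is stable).
knn_indices <- function(dmat, i, k) {
  d <- dmat[i, ]
  d[i] <- Inf
  order(d)[seq_len(k)]
}
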