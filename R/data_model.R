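# Core data types: expression matrices, Gleason labels, and their readers.
#
# An expression matrix is stored as a plain numeric matrix in samples x
# features orientation, with sample IDs as rownames and feature IDs as
# colnames. Values are TPM (or log2(TPM+1) after ingestion); the orientation
# is fixed internally and never guessed from a file.

.gleason_table <- c(
  "6"     = 1L,
  "3+4=7" = 2L,
  "4+3=7" = 3L,
  "8"     = 4L,
  "9"     = 5L,
  "10"    = 5L
)

#' Map a Gleason score string to its Gleason group
#'
#' Implements the five-level Epstein grouping of Gleason scores:
#' score 6 is group 1, 3+4=7 is group 2, 4+3=7 is group 3, 8 is group 4,
#' and 9 or 10 are group 5. Score strings are whitespace-insensitive, so
#' `"3 + 4 = 7"` and `"3+4=7"` are equivalent; the bare primary/secondary
#' form `"3+4"` is also accepted. Scores 2-5 are no longer assigned in
#' modern pathology and are rejected.
#'
#' @param raw_score character vector of score strings
#'   (e.g. `"6"`, `"3+4=7"`, `"9"`).
#' @return integer vector of Gleason groups in 1..5.
#' @examples
#' map_gleason_score_to_group(c("6", "3 + 4 = 7", "10"))
#' @export
map_gleason_score_to_group <- function(raw_score) {
  if (length(raw_score) == 0L) stopf("no Gleason score strings supplied")
  key <- gsub("[[:space:]]+", "", as.character(raw_score))
  # "3+4" and "4+3" are the "=7" forms with the sum elided
  key[key == "3+4"] <- "3+4=7"
  key[key == "4+3"] <- "4+3=7"
  grp <- .gleason_table[key]
  if (anyNA(grp)) {
    bad <- unique(raw_score[is.na(grp)])
    stopf(
      "unrecognised Gleason score string(s): %s (recognised: %s)",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(names(.gleason_table)), collapse = ", ")
    )
  }
  unname(grp)
}

#' Validate a samples-by-features expression matrix
#'
#' Checks the invariants every downstream stage relies on: numeric,
#' finite, non-negative values and duplicate-free sample and feature IDs.
#'
#' @param m numeric matrix, samples in rows, features in columns, with
#'   rownames (sample IDs) and colnames (feature IDs).
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stopf("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stopf("expression matrix must carry sample IDs (rownames) and feature IDs (colnames)")
  }
  if (anyDuplicated(rownames(m))) {
    stopf("duplicated sample IDs: %s",
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stopf("duplicated feature IDs: %s",
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stopf("non-finite or negative expression value at row %d (%s), column %d (%s)",
          rc[1L], rownames(m)[rc[1L]], rc[2L], colnames(m)[rc[2L]])
  }
  invisible(m)
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV body with a header row of IDs and a first column of IDs
#' (GCT-style body without the GCT header). Files are commonly written
#' features-by-samples; the `orientation` flag states which way the file is
#' laid out — it is never guessed. The matrix is returned in the package's
#' internal samples-by-features orientation.
#'
#' By default values are log2(x+1)-transformed at ingestion, which is the
#' scale all downstream modelling in this package assumes for TPM input;
#' pass `log2_transform = FALSE` for data already on a log-like scale.
#'
#' @param path file path.
#' @param orientation `"features_by_samples"` (default; rows are features) or
#'   `"samples_by_features"`.
#' @param sep field separator; `"\t"` by default, `","` for CSV.
#' @param log2_transform apply log2(x+1) to the values (default `TRUE`).
#' @return numeric matrix, samples x features.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_by_samples",
                                                   "samples_by_features"),
                                   sep = "\t",
                                   log2_transform = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("expression matrix file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", row.names = NULL,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stopf("%s: expected an ID column plus at least one value column", path)
  ids <- df[[1L]]
  header_ids <- names(df)[-1L]  # captured before subsetting uniquifies them
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("%s: non-numeric cell '%s' at data row %d (id %s), column '%s'",
          path, as.character(body[bad[1L], bad[2L]]), bad[1L], ids[bad[1L]],
          colnames(body)[bad[2L]])
  }
  rownames(vals) <- ids
  colnames(vals) <- header_ids
  m <- if (orientation == "features_by_samples") t(vals) else vals
  if (log2_transform) {
    if (any(m < 0, na.rm = TRUE)) stopf("%s: negative values; cannot log2(x+1)-transform", path)
    m <- log2(m + 1)
  }
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression_matrix()] (without the log transform):
#' writes the matrix in the requested file orientation with an ID header.
#'
#' @inheritParams read_expression_matrix
#' @param m samples x features numeric matrix.
#' @export
write_expression_matrix <- function(m, path,
                                    orientation = c("features_by_samples",
                                                    "samples_by_features"),
                                    sep = "\t") {
  orientation <- match.arg(orientation)
  validate_expression_matrix(m)
  out <- if (orientation == "features_by_samples") t(m) else m
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (orientation == "features_by_samples") "feature_id" else "sample_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label file
#'
#' Two-column delimited file: sample ID, Gleason score string. A header line
#' is detected by attempting to parse the first row's score; files with or
#' without a header are both accepted. Scores are converted to Gleason
#' groups via [map_gleason_score_to_group()].
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame with columns `sample_id`, `score`, `group`, in file
#'   order.
#' @export
read_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  if (file.size(path) == 0L) stopf("%s: label file is empty", path)
  df <- utils::read.table(path, header = FALSE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"", blank.lines.skip = TRUE)
  if (nrow(df) == 0L) stopf("%s: label file is empty", path)
  if (ncol(df) < 2L) stopf("%s: expected two columns (sample_id, score)", path)
  first_parses <- tryCatch(
    { map_gleason_score_to_group(df[1L, 2L]); TRUE },
    error = function(e) FALSE
  )
  if (!first_parses) {
    if (nrow(df) == 1L) stopf("%s: no parsable label rows", path)
    df <- df[-1L, , drop = FALSE]  # header line
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stopf("%s: duplicated sample IDs in label file: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(
    sample_id = ids,
    score = df[[2L]],
    group = map_gleason_score_to_group(df[[2L]]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Align a label table with an expression matrix
#'
#' Errors if any sample is present on one side only (listing the missing
#' IDs), otherwise returns the integer group vector ordered like the matrix
#' rows.
#'
#' @param m samples x features expression matrix.
#' @param labels data.frame from [read_labels()] (or with columns
#'   `sample_id`, `group`).
#' @return named integer vector of groups, one per matrix row.
#' @export
align_labels <- function(m, labels) {
  ms <- rownames(m)
  ls <- labels$sample_id
  miss_lab <- setdiff(ms, ls)
  miss_mat <- setdiff(ls, ms)
  if (length(miss_lab) || length(miss_mat)) {
    stopf(paste0(
      "sample ID mismatch between matrix and labels.",
      if (length(miss_lab)) sprintf(" Missing from labels: %s.", paste(miss_lab, collapse = ", ")) else "",
      if (length(miss_mat)) sprintf(" Missing from matrix: %s.", paste(miss_mat, collapse = ", ")) else ""
    ))
  }
  g <- as.integer(labels$group[match(ms, ls)])
  names(g) <- ms
  g
}
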