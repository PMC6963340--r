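# Node classifiers: Gaussian naive Bayes and linear-kernel SVM.
#
# Models are fitted with e1071 and immediately reduced to plain numeric
# parameters (class priors + per-class feature means/sds for NB; a weight
# vector and intercept for the linear SVM). Prediction runs off those
# parameters only, which makes node models JSON-serializable and makes a
# loaded model's predictions bit-identical to the in-memory ones.

node_classifier_kinds <- function() c("gaussian-nb", "linear-svm")

#' Fit a binary node classifier
#'
#' @param kind `"gaussian-nb"` or `"linear-svm"`.
#' @param X samples x features numeric matrix (the selected feature subset).
#' @param y binary 0/1 vector; 1 is the positive class.
#' @return list of class `node_classifier` holding the kind, the feature
#'   IDs, and the numeric parameters needed for prediction.
#' @export
fit_node_classifier <- function(kind, X, y) {
  kind <- match.arg(kind, node_classifier_kinds())
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stopf("node classifiers require both classes in training data")
  feats <- colnames(X) %||% sprintf("f%05d", seq_len(ncol(X)))
  colnames(X) <- feats

  if (kind == "gaussian-nb") {
    fit <- e1071::naiveBayes(x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)))
    mu <- vapply(fit$tables, function(tb) tb[, 1L], numeric(2L))  # 2 x p means
    sd_ <- vapply(fit$tables, function(tb) tb[, 2L], numeric(2L)) # 2 x p sds
    # variance floor keeps constant features from producing infinite densities
    var_ <- sd_^2
    var_[!is.finite(var_)] <- 0  # single-sample class: sd is undefined
    eps <- 1e-9 * max(var_, 1e-12)
    params <- list(
      prior = as.numeric(fit$apriori / sum(fit$apriori)),  # P(y=0), P(y=1)
      mean = unname(mu), var = unname(var_ + eps)
    )
  } else {
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                      kernel = "linear", scale = FALSE, cost = 1)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm orients decision values toward whichever class it saw first;
    # fix the sign empirically so a positive score means the positive class
    s <- as.numeric(X %*% w) + b
    pred_lab <- as.integer(as.character(stats::predict(fit, X)))
    if (mean((s > 0) == (pred_lab == 1L)) < 0.5) { w <- -w; b <- -b }
    params <- list(w = w, b = b)
  }

  structure(list(kind = kind, features = feats, params = params),
            class = "node_classifier")
}

#' Decision scores of a node classifier
#'
#' Higher scores favour the positive class. For naive Bayes the score is
#' the log-posterior difference `log P(1|x) - log P(0|x)`; for the linear
#' SVM it is the signed margin.
#'
#' @param clf a `node_classifier`.
#' @param X samples x features matrix containing at least the classifier's
#'   features (by name).
#' @return numeric score per row.
#' @export
predict_node_score <- function(clf, X) {
  stopifnot(inherits(clf, "node_classifier"))
  missing <- setdiff(clf$features, colnames(X))
  if (length(missing)) {
    stopf("prediction matrix is missing feature(s): %s",
          paste(missing, collapse = ", "))
  }
  Xs <- as.matrix(X[, clf$features, drop = FALSE])
  if (clf$kind == "gaussian-nb") {
    p <- clf$params
    loglik <- function(cls) {
      mu <- p$mean[cls, ]; v <- p$var[cls, ]
      rowSums(sweep(sweep(Xs, 2L, mu)^2, 2L, -2 * v, "/") -
                matrix(0.5 * log(2 * pi * v), nrow(Xs), ncol(Xs), byrow = TRUE))
    }
    (loglik(2L) + log(p$prior[2L])) - (loglik(1L) + log(p$prior[1L]))
  } else {
    as.numeric(Xs %*% clf$params$w + clf$params$b)
  }
}

#' Hard class call of a node classifier
#'
#' @inheritParams predict_node_score
#' @param threshold score cut-off (default 0).
#' @return integer 0/1 vector.
#' @export
predict_node_class <- function(clf, X, threshold = 0) {
  as.integer(predict_node_score(clf, X) > threshold)
}
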