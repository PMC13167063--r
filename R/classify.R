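# Classifier families. All four share one contract: train() returns a
# notesieve_model whose predict_proba() gives the probability of the
# positive ("relevant") class, in [0, 1]; the two binary class scores are
# complementary by construction.

FAMILIES <- c("rf", "gbt", "knn", "ncd_knn")

# normalize assorted label encodings to logical is-positive
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop_user("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- tolower(as.character(labels))
  pos <- lab %in% c("relevant", "positive", "1", "true", "yes")
  neg <- lab %in% c("irrelevant", "negative", "0", "false", "no")
  if (!all(pos | neg)) {
    stop_user("unrecognized label value(s): %s",
              paste(unique(lab[!(pos | neg)]), collapse = ", "))
  }
  pos
}

as_feature_matrix <- function(features) {
  if (inherits(features, "notesieve_features")) features <- features$matrix
  if (inherits(features, "Matrix")) features <- as.matrix(features)
  if (!is.matrix(features)) stop_user("features must be a matrix or notesieve_features")
  storage.mode(features) <- "double"
  features
}

#' Train a relevance classifier
#'
#' @param family one of `"rf"` (random forest), `"gbt"` (gradient boosted
#'   trees, logistic loss), `"knn"` (k-nearest neighbours on feature
#'   vectors), or `"ncd_knn"` (k-NN on normalized compression distance over
#'   raw texts).
#' @param features a `notesieve_features` or numeric matrix; for
#'   `"ncd_knn"`, a character vector of raw texts.
#' @param labels document labels; `"relevant"`/`"irrelevant"`, logical,
#'   or 0/1. Both classes must be present.
#' @param hyperparams named list of hyperparameters; unspecified entries
#'   take the family defaults (see [hyper_grid()] for the tuning axes).
#' @param seed integer seed controlling all training randomness.
#' @return an object of class `notesieve_model`.
#' @export
train <- function(family, features, labels, hyperparams = list(), seed = 1L) {
  family <- match.arg(family, FAMILIES)
  y <- as_positive(labels)
  if (length(unique(y)) < 2L) {
    stop_user("training error: labels contain a single class")
  }
  hp <- utils::modifyList(default_hyperparams(family), hyperparams)
  if (family == "ncd_knn") {
    if (!is.character(features)) {
      stop_user("ncd_knn trains on raw texts (character vector)")
    }
    if (length(features) != length(y)) stop_user("features/labels length mismatch")
    fit <- list(texts = features, y = y,
                ref_lengths = compressed_length(features))
    dims <- NULL
  } else {
    X <- as_feature_matrix(features)
    if (nrow(X) != length(y)) stop_user("features/labels row mismatch")
    dims <- colnames(X)
    fit <- switch(family,
      rf = list(trees = cpp_rf_fit(X, as.integer(y),
                                   as.integer(hp$n_trees),
                                   depth_or_zero(hp$max_depth),
                                   as.integer(hp$min_samples_split),
                                   as.integer(hp$min_samples_leaf),
                                   hp$feature_strategy,
                                   identical(hp$class_weight, "balanced"),
                                   as.integer(seed))),
      gbt = list(trees = cpp_gbt_fit(X, as.integer(y),
                                     as.integer(hp$n_estimators),
                                     hp$learning_rate,
                                     as.integer(hp$max_depth),
                                     hp$min_child_weight, hp$subsample,
                                     hp$colsample_bytree, hp$lambda,
                                     as.integer(seed)),
                 eta = hp$learning_rate),
      knn = list(X = X, y = y))
  }
  structure(list(family = family, fit = fit, hyperparams = hp,
                 seed = as.integer(seed), n_features = length(dims),
                 col_names = dims,
                 representation = if (inherits(features, "notesieve_features"))
                   features$representation else NULL),
            class = "notesieve_model")
}

depth_or_zero <- function(d) {
  if (is.null(d) || is.na(d) || identical(d, "none")) 0L else as.integer(d)
}

default_hyperparams <- function(family) {
  switch(family,
    rf = list(n_trees = 300L, max_depth = NA, min_samples_split = 2L,
              min_samples_leaf = 1L, feature_strategy = "sqrt",
              class_weight = "none"),
    gbt = list(learning_rate = 0.1, n_estimators = 100L, max_depth = 3L,
               min_child_weight = 1, subsample = 1.0, colsample_bytree = 1.0,
               lambda = 1.0),
    knn = list(k = 5L, weights = "uniform", metric = "euclidean",
               minkowski_p = 3, leaf_size = 30L),
    ncd_knn = list(k = 5L, weights = "uniform"))
}

#' @export
print.notesieve_model <- function(x, ...) {
  cat(sprintf("<notesieve_model [%s]%s, seed %d>\n", x$family,
              if (!is.null(x$representation))
                paste0(" on ", x$representation) else "", x$seed))
  invisible(x)
}

#' Predict relevance probabilities
#'
#' @param model a `notesieve_model`.
#' @param features features in the same space the model was trained on
#'   (raw texts for `"ncd_knn"`).
#' @return numeric vector of probabilities of the relevant class, in
#'   `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "notesieve_model"))
  if (model$family == "ncd_knn") {
    if (!is.character(features)) stop_user("ncd_knn predicts on raw texts")
    return(ncd_knn_classify(model$fit$texts, model$fit$y, features,
                            k = model$hyperparams$k,
                            weights = model$hyperparams$weights,
                            ref_lengths = model$fit$ref_lengths))
  }
  X <- as_feature_matrix(features)
  if (ncol(X) != model$n_features) {
    stop_user("feature-space error: model expects %d columns, got %d",
              model$n_features, ncol(X))
  }
  p <- switch(model$family,
    rf = cpp_rf_predict(model$fit$trees, X),
    gbt = cpp_gbt_predict(model$fit$trees, X, model$fit$eta),
    knn = knn_proba(model$fit$X, model$fit$y, X, model$hyperparams))
  pmin(pmax(as.numeric(p), 0), 1)
}

# brute-force k-NN vote; leaf_size is accepted for interface parity but has
# no effect (no tree index is built at these scales)
knn_proba <- function(Xtr, y, Xq, hp) {
  k <- min(as.integer(hp$k), nrow(Xtr))
  D <- pair_dist(Xq, Xtr, hp$metric, hp$minkowski_p %||% 3)
  apply_knn_vote(D, y, k, hp$weights)
}

pair_dist <- function(A, B, metric, p = 3) {
  metric <- match.arg(metric, c("euclidean", "manhattan", "minkowski"))
  n <- nrow(A); m <- nrow(B)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
      2 * tcrossprod(A, B)
    return(sqrt(pmax(d2, 0)))
  }
  out <- matrix(0, n, m)
  pw <- if (metric == "manhattan") 1 else p
  for (i in seq_len(n)) {
    diffs <- abs(sweep(B, 2, A[i, ], "-"))^pw
    out[i, ] <- rowSums(diffs)^(1 / pw)
  }
  out
}

apply_knn_vote <- function(D, y, k, weights = "uniform") {
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    nb <- order(d)[seq_len(k)]          # stable: distance ties break by index
    if (identical(weights, "distance")) {
      dn <- d[nb]
      if (any(dn == 0)) {
        mean(y[nb][dn == 0])
      } else {
        w <- 1 / dn
        sum(w * y[nb]) / sum(w)
      }
    } else {
      mean(y[nb])
    }
  }, numeric(1))
}
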