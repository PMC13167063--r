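#' Grid search with stratified k-fold cross-validation
#'
#' Evaluates every candidate in the grid with stratified k-fold
#' cross-validation, scoring F1, precision, recall and specificity of the
#' positive class on each held-out fold (class labels at probability 0.5).
#' The winner maximizes mean F1; ties break to higher mean recall, then to
#' first position in grid order.
#'
#' @param family classifier family, see [train()].
#' @param features features (raw texts for `"ncd_knn"`).
#' @param labels document labels.
#' @param grid a `notesieve_grid` or named list of candidate vectors; by
#'   default the family's `"default"` grid from [hyper_grid()].
#' @param folds number of folds (default 5).
#' @param seed seed for fold shuffling and fold-model training.
#' @return an object of class `notesieve_cv`: `scores` (per-candidate,
#'   per-fold data.frame), `summary` (per-candidate means), `best` (the
#'   selected hyperparameter list), `best_index`, `selection_metric`.
#' @export
grid_search <- function(family, features, labels, grid = NULL, folds = 5L,
                        seed = 1L) {
  family <- match.arg(family, FAMILIES)
  grid <- grid %||% hyper_grid(family)
  candidates <- expand_grid_candidates(grid)
  y <- as_positive(labels)
  n <- length(y)
  if (min(table(y)) < folds) {
    stop_user("CV error: need at least %d samples per class for %d stratified folds",
              folds, folds)
  }
  fold_id <- stratified_folds(y, folds, seed)
  texts <- if (family == "ncd_knn") features else NULL
  X <- if (family == "ncd_knn") NULL else as_feature_matrix(features)

  rows <- list()
  for (ci in seq_along(candidates)) {
    hp <- candidates[[ci]]
    for (f in seq_len(folds)) {
      test_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      if (family == "ncd_knn") {
        m <- train(family, texts[train_idx], y[train_idx], hp,
                   seed = derive_seed(seed, paste0("fold", f)))
        p <- predict_proba(m, texts[test_idx])
      } else {
        m <- train(family, X[train_idx, , drop = FALSE], y[train_idx], hp,
                   seed = derive_seed(seed, paste0("fold", f)))
        p <- predict_proba(m, X[test_idx, , drop = FALSE])
      }
      cm <- confusion(y[test_idx], p >= 0.5)
      ms <- compute_metrics(cm)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = ci, fold = f, f1 = ms$f1, precision = ms$precision,
        recall = ms$recall, specificity = ms$specificity)
    }
  }
  scores <- do.call(rbind, rows)
  agg <- stats::aggregate(scores[c("f1", "precision", "recall", "specificity")],
                          by = list(candidate = scores$candidate), FUN = mean)
  agg <- agg[order(agg$candidate), ]
  # argmax mean F1; ties -> higher mean recall -> first in grid order
  best_f1 <- max(agg$f1)
  tied <- which(agg$f1 >= best_f1 - 1e-12)
  best_index <- tied[order(-agg$recall[tied], tied)][1]
  structure(list(scores = scores, summary = agg,
                 candidates = candidates,
                 best = candidates[[best_index]],
                 best_index = as.integer(best_index),
                 selection_metric = "f1",
                 family = family, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "notesieve_cv")
}

#' @export
print.notesieve_cv <- function(x, ...) {
  b <- x$summary[x$best_index, ]
  cat(sprintf("<notesieve_cv [%s]: %d candidates x %d folds; best mean F1 %.3f (P %.3f, R %.3f)>\n",
              x$family, length(x$candidates), x$folds, b$f1, b$precision, b$recall))
  cat("best:", paste(names(x$best), vapply(x$best, format, character(1)),
                     sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}
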