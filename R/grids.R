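#' Hyperparameter grids
#'
#' Default grids discretize the standard tuning ranges for each family:
#' random forest trees 100-500, depth 10-30 or unlimited, split/leaf
#' minimums, feature strategy, class weights; boosting learning rate
#' 0.01-0.3, rounds 100-1000, depth 3-10, child weight 1-6, row/column
#' subsampling 0.5-1.0; k-NN neighbours 1-19, uniform or distance weights,
#' Euclidean/Manhattan/Minkowski(p=3) metrics, leaf size 10-50. The full
#' grids are large (720 candidates for the forest); the `"fast"` preset
#' keeps two values on the two most influential axes and pins the rest at
#' their defaults, sized for continuous-integration runs.
#'
#' @param family classifier family, see [train()].
#' @param preset `"default"` or `"fast"`.
#' @return a named list of candidate vectors, class `notesieve_grid`.
#' @export
hyper_grid <- function(family, preset = c("default", "fast")) {
  family <- match.arg(family, FAMILIES)
  preset <- match.arg(preset)
  g <- if (preset == "default") {
    switch(family,
      rf = list(n_trees = c(100L, 200L, 300L, 400L, 500L),
                max_depth = c(10L, 20L, 30L, NA),
                min_samples_split = c(2L, 5L, 10L),
                min_samples_leaf = c(1L, 2L, 4L),
                feature_strategy = c("sqrt", "log2"),
                class_weight = c("none", "balanced")),
      gbt = list(learning_rate = c(0.01, 0.05, 0.1, 0.3),
                 n_estimators = c(100L, 300L, 500L, 1000L),
                 max_depth = c(3L, 6L, 10L),
                 min_child_weight = c(1, 3, 6),
                 subsample = c(0.5, 0.75, 1.0),
                 colsample_bytree = c(0.5, 0.75, 1.0)),
      knn = list(k = seq(1L, 19L, by = 2L),
                 weights = c("uniform", "distance"),
                 metric = c("euclidean", "manhattan", "minkowski"),
                 leaf_size = c(10L, 30L, 50L)),
      ncd_knn = list(k = seq(1L, 19L, by = 2L),
                     weights = "uniform"))
  } else {
    switch(family,
      rf = list(n_trees = c(100L, 200L), max_depth = c(10L, NA)),
      gbt = list(learning_rate = c(0.1, 0.3), n_estimators = c(100L, 300L)),
      knn = list(k = c(5L, 15L), weights = c("uniform", "distance")),
      ncd_knn = list(k = c(5L, 15L)))
  }
  structure(g, class = "notesieve_grid", family = family, preset = preset)
}

# expand a grid (named list of vectors) into a list of hyperparameter lists,
# in column-major grid order (first axis varies fastest)
expand_grid_candidates <- function(grid) {
  stopifnot(is.list(grid), length(grid) > 0)
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    as.list(df[i, , drop = FALSE])
  })
}
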