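#' Classify texts by k-nearest neighbours under compression distance
#'
#' The parameter-free compression classifier: each query's distance to every
#' training text is the normalized compression distance ([ncd()]); its
#' relevance probability is the fraction of positive labels among the `k`
#' nearest references (uniform weights by default; distance ties break by
#' reference order). No features, no training — the "model" is the training
#' texts themselves.
#'
#' @param train_texts character vector of reference texts.
#' @param train_labels labels aligned with `train_texts`.
#' @param query_texts character vector of texts to classify.
#' @param k number of neighbours (`k <= length(train_texts)`).
#' @param weights `"uniform"` (default) or `"distance"`.
#' @param ref_lengths optional precomputed compressed lengths of
#'   `train_texts`.
#' @return numeric vector of positive-class probabilities.
#' @export
ncd_knn_classify <- function(train_texts, train_labels, query_texts, k = 5L,
                             weights = "uniform", ref_lengths = NULL) {
  if (length(train_texts) == 0) stop_user("empty training set")
  y <- as_positive(train_labels)
  if (length(y) != length(train_texts)) stop_user("texts/labels length mismatch")
  if (k > length(train_texts)) {
    stop_user("k=%d exceeds training size %d", k, length(train_texts))
  }
  D <- ncd_distance_matrix(query_texts, train_texts, ref_lengths = ref_lengths)
  apply_knn_vote(D, y, as.integer(k), weights)
}
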