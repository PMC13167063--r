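#' Confusion matrix for binary relevance
#'
#' `tp` counts gold-relevant documents predicted relevant; `tn` counts
#' gold-irrelevant documents predicted irrelevant.
#'
#' @param gold_labels,predicted_labels aligned label vectors (any encoding
#'   accepted by the package: `"relevant"`/`"irrelevant"`, logical, 0/1).
#' @return an object of class `notesieve_confusion` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(gold_labels, predicted_labels) {
  if (length(gold_labels) != length(predicted_labels)) {
    stop_user("gold and predicted label lengths differ (%d vs %d)",
              length(gold_labels), length(predicted_labels))
  }
  g <- as_positive(gold_labels)
  p <- as_positive(predicted_labels)
  structure(list(tp = sum(g & p), fp = sum(!g & p),
                 fn = sum(g & !p), tn = sum(!g & !p)),
            class = "notesieve_confusion")
}

#' @export
print.notesieve_confusion <- function(x, ...) {
  cat(sprintf("          predicted+  predicted-\n gold+    %9d  %9d\n gold-    %9d  %9d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' and F1 (harmonic mean of precision and recall), all for the positive
#' (relevant) class. A zero denominator yields 0 with the corresponding
#' `undefined` flag set, so threshold sweeps never abort.
#'
#' @param cm a `notesieve_confusion`, or a list with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @return an object of class `notesieve_metrics`: `precision`, `recall`,
#'   `specificity`, `f1`, and logical vector `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  safe_div <- function(num, den) {
    if (den == 0) list(v = 0, undef = TRUE) else list(v = num / den, undef = FALSE)
  }
  pr <- safe_div(cm$tp, cm$tp + cm$fp)
  rc <- safe_div(cm$tp, cm$tp + cm$fn)
  sp <- safe_div(cm$tn, cm$tn + cm$fp)
  f1 <- if (!pr$undef && !rc$undef && (pr$v + rc$v) > 0) {
    list(v = 2 * pr$v * rc$v / (pr$v + rc$v), undef = FALSE)
  } else {
    list(v = 0, undef = TRUE)
  }
  structure(list(precision = pr$v, recall = rc$v, specificity = sp$v,
                 f1 = f1$v,
                 undefined = c(precision = pr$undef, recall = rc$undef,
                               specificity = sp$undef, f1 = f1$undef)),
            class = "notesieve_metrics")
}

#' @export
print.notesieve_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("precision %.*f | recall %.*f | specificity %.*f | F1 %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$specificity,
              digits, x$f1))
  invisible(x)
}

#' Sweep the decision threshold from 0 to 1
#'
#' At each threshold `t` in 0.0, 0.1, ..., 1.0 a document is predicted
#' relevant iff its probability is `>= t` (so the 0.0 row predicts
#' everything relevant and anchors recall at 1). Returns the full metric
#' set per threshold.
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param gold_labels aligned gold labels.
#' @return a data.frame of class `notesieve_threshold_table` with 11 rows:
#'   `threshold`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `specificity`, `f1`, `n_predicted_positive`.
#' @export
threshold_sweep <- function(probabilities, gold_labels) {
  if (length(probabilities) != length(gold_labels)) {
    stop_user("probabilities and labels lengths differ")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop_user("probabilities must lie in [0, 1]")
  }
  g <- as_positive(gold_labels)
  thresholds <- seq(0, 1, by = 0.1)
  rows <- lapply(thresholds, function(t) {
    pred <- probabilities >= t
    cm <- confusion(g, pred)
    ms <- compute_metrics(cm)
    data.frame(threshold = t, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
               precision = ms$precision, recall = ms$recall,
               specificity = ms$specificity, f1 = ms$f1,
               n_predicted_positive = cm$tp + cm$fp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("notesieve_threshold_table", "data.frame")
  out
}

#' Select the operating threshold from a sweep
#'
#' Argmax of F1; ties break to higher recall, then to the lower threshold.
#' With `min_recall` set, the argmax is restricted to rows meeting the
#' recall floor (falling back to the unrestricted rule if none do).
#'
#' @param table a `notesieve_threshold_table`.
#' @param min_recall optional recall floor in `[0, 1]`.
#' @return the selected threshold (scalar).
#' @export
select_threshold <- function(table, min_recall = NULL) {
  stopifnot(nrow(table) > 0)
  cand <- seq_len(nrow(table))
  if (!is.null(min_recall)) {
    ok <- which(table$recall >= min_recall)
    if (length(ok)) cand <- ok
  }
  f1 <- table$f1[cand]
  rec <- table$recall[cand]
  best <- cand[order(-f1, -rec, table$threshold[cand])][1]
  table$threshold[best]
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples document indices with replacement, recomputes the statistic on
#' each replicate, and reports the 2.5th/97.5th percentiles. If the
#' statistic is undefined (zero denominator) in more than half of the
#' replicates, a `degenerate` flag is set on the result.
#'
#' @param gold_labels,predicted_labels aligned label vectors.
#' @param statistic `"f1"`, `"precision"`, `"recall"`, or `"specificity"`.
#' @param iterations bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return an object of class `notesieve_ci`: `statistic`, `point`,
#'   `lower`, `upper`, `iterations`, `seed`, `degenerate`.
#' @export
bootstrap_ci <- function(gold_labels, predicted_labels, statistic = "f1",
                         iterations = 1000L, seed = 1L, conf = 0.95) {
  statistic <- match.arg(statistic,
                         c("f1", "precision", "recall", "specificity"))
  if (iterations < 1) stop_user("iterations must be >= 1")
  g <- as_positive(gold_labels)
  p <- as_positive(predicted_labels)
  if (length(g) != length(p)) stop_user("label lengths differ")
  stat_of <- function(idx) {
    ms <- compute_metrics(confusion(g[idx], p[idx]))
    c(value = ms[[statistic]], undef = ms$undefined[[statistic]])
  }
  point <- stat_of(seq_along(g))
  reps <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(iterations), function(b) {
      stat_of(sample.int(length(g), replace = TRUE))
    }, numeric(2))
  })
  vals <- reps[1, ]
  undef_frac <- mean(reps[2, ] > 0)
  qs <- stats::quantile(vals, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(statistic = statistic, point = unname(point[1]),
                 lower = qs[1], upper = qs[2],
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 degenerate = undef_frac > 0.5),
            class = "notesieve_ci")
}

#' @export
print.notesieve_ci <- function(x, ...) {
  cat(sprintf("%s %.3f (95%% CI %.3f-%.3f; %d bootstrap iterations%s)\n",
              x$statistic, x$point, x$lower, x$upper, x$iterations,
              if (x$degenerate) "; DEGENERATE" else ""))
  invisible(x)
}

#' Evaluate the diagnosis-code heuristic baseline on a gold set
#'
#' The baseline predicts a note relevant iff its silver pool is
#' `COPD_ENCOUNTER` (i.e. its encounter carries a target code). Every gold
#' note must have a pool assignment.
#'
#' @param pools pool assignment data.frame from [build_pools()] (columns
#'   `note_id`, `pool`).
#' @param gold_test gold annotations: data.frame with `note_id`, `label`.
#' @param iterations,seed bootstrap settings for the F1 confidence interval.
#' @return list with `confusion`, `metrics`, `ci` (bootstrap F1 CI), and
#'   `predictions`.
#' @export
evaluate_baseline <- function(pools, gold_test, iterations = 1000L, seed = 1L) {
  stopifnot(all(c("note_id", "label") %in% names(gold_test)))
  idx <- match(gold_test$note_id, pools$note_id)
  if (anyNA(idx)) {
    stop_user("gold note(s) missing from pool assignment: %s",
              paste(utils::head(gold_test$note_id[is.na(idx)], 3), collapse = ", "))
  }
  pred <- pools$pool[idx] == "COPD_ENCOUNTER"
  cm <- confusion(gold_test$label, pred)
  list(confusion = cm, metrics = compute_metrics(cm),
       ci = bootstrap_ci(gold_test$label, pred, "f1", iterations, seed),
       predictions = data.frame(note_id = gold_test$note_id,
                                predicted = ifelse(pred, "relevant", "irrelevant"),
                                stringsAsFactors = FALSE))
}
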