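#' Experiment configuration
#'
#' One experiment = one config = one report. A config names the inputs
#' (corpus and gold files or in-memory objects), one text representation,
#' one classifier family with a grid preset, the training-subset design,
#' the seeds for each stochastic stage, and the threshold-selection mode.
#'
#' @param corpus a `notesieve_corpus` or path to a notes JSONL file.
#' @param gold gold annotations: data.frame or CSV path.
#' @param representation `"embedding"`, `"bow"`, `"tfidf"`, `"compression"`,
#'   or `"concept"`.
#' @param family `"rf"`, `"gbt"`, `"knn"`, or `"ncd_knn"` (the latter
#'   ignores `representation` and works on raw text).
#' @param grid_preset `"default"` or `"fast"`; or pass a `grid` list
#'   explicitly.
#' @param grid optional explicit hyperparameter grid (overrides
#'   `grid_preset`).
#' @param subset a `notesieve_subset_config`; its `n_pos` must be
#'   achievable on the corpus.
#' @param codeset a `notesieve_codeset` or path to a codeset JSON.
#' @param lexicon a `notesieve_lexicon` or path to a lexicon TSV (required
#'   for `representation = "concept"`).
#' @param lookback_months silver-labeling lookback.
#' @param validation_n gold documents used for threshold calibration; the
#'   rest form the test set.
#' @param min_recall optional recall floor for threshold selection.
#' @param representation_params named list forwarded to the representation
#'   fitter (e.g. `dim`, `epochs` for embeddings; `min_df` for counts).
#' @param bootstrap_iterations bootstrap replicates for test-set CIs.
#' @param seeds named list with `sampling`, `training`, `bootstrap`, `split`.
#' @return a list of class `notesieve_config`.
#' @export
run_config <- function(corpus, gold,
                       representation = c("embedding", "bow", "tfidf",
                                          "compression", "concept"),
                       family = c("rf", "gbt", "knn", "ncd_knn"),
                       grid_preset = c("fast", "default"), grid = NULL,
                       subset = subset_config("MIXED", n_pos = 100L),
                       codeset = copd_codeset(), lexicon = NULL,
                       lookback_months = 24L, validation_n = 84L,
                       min_recall = NULL, representation_params = list(),
                       bootstrap_iterations = 1000L,
                       seeds = list(sampling = 13L, training = 1L,
                                    bootstrap = 7L, split = 7L)) {
  representation <- match.arg(representation)
  family <- match.arg(family)
  grid_preset <- match.arg(grid_preset)
  if (is.character(codeset)) codeset <- read_codeset(codeset)
  if (representation == "concept") {
    if (is.null(lexicon)) {
      stop_user("configuration error: representation 'concept' requires a lexicon")
    }
    if (is.character(lexicon)) {
      if (!file.exists(lexicon)) {
        stop_user("configuration error: lexicon file '%s' not found", lexicon)
      }
      lexicon <- read_lexicon(lexicon)
    }
  }
  if (is.character(corpus)) {
    if (!file.exists(corpus)) {
      stop_user("configuration error: corpus file '%s' not found", corpus)
    }
  }
  if (is.character(gold)) {
    if (!file.exists(gold)) {
      stop_user("configuration error: gold file '%s' not found", gold)
    }
  }
  structure(list(corpus = corpus, gold = gold, representation = representation,
                 family = family, grid_preset = grid_preset, grid = grid,
                 subset = subset, codeset = codeset, lexicon = lexicon,
                 lookback_months = as.integer(lookback_months),
                 validation_n = as.integer(validation_n),
                 min_recall = min_recall,
                 representation_params = representation_params,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 seeds = seeds),
            class = "notesieve_config")
}

#' Run the full weak-supervision experiment
#'
#' Executes label -> subset -> featurize -> grid-search -> train ->
#' calibrate-on-validation -> evaluate-on-test and returns a single report.
#' Identical config and seeds give identical reports (up to the timestamp
#' field).
#'
#' @param config a `notesieve_config`.
#' @param report_path optional path; when given, the report is written as
#'   JSON.
#' @param quiet suppress progress messages (default TRUE).
#' @return a list of class `notesieve_report`.
#' @export
run_experiment <- function(config, report_path = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "notesieve_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  corpus <- if (is.character(config$corpus)) {
    read_corpus(config$corpus, config$codeset)
  } else {
    config$corpus
  }
  gold <- if (is.character(config$gold)) read_gold(config$gold) else config$gold

  say("label", "building silver pools")
  pools <- build_pools(corpus, config$codeset, config$lookback_months)
  say("label", "pool counts: %s",
      paste(names(attr(pools, "report")), unlist(attr(pools, "report")),
            sep = "=", collapse = ", "))

  say("subset", "sampling %s training subset (n_pos=%d)", config$subset$name,
      config$subset$n_pos)
  train_docs <- sample_training_subset(pools, corpus, config$subset)

  split <- split_gold(gold, pools, config$validation_n,
                      seed = config$seeds$split %||% 7L)
  gold_val <- split$validation
  gold_test <- split$test
  note_text <- function(ids) corpus$notes$text[match(ids, corpus$notes$note_id)]

  say("featurize", "representation %s", config$representation)
  train_seed <- config$seeds$training %||% 1L
  if (config$family == "ncd_knn") {
    Xtr <- train_docs$text
    Xval <- note_text(gold_val$note_id)
    Xte <- note_text(gold_test$note_id)
  } else {
    feats <- featurize_splits(config, train_docs, gold_val, gold_test,
                              note_text, train_seed)
    Xtr <- feats$train; Xval <- feats$validation; Xte <- feats$test
  }

  say("train", "grid search (%s, preset %s)", config$family, config$grid_preset)
  grid <- config$grid %||% hyper_grid(config$family, config$grid_preset)
  cv <- grid_search(config$family, Xtr, train_docs$label, grid,
                    folds = 5L, seed = train_seed)
  model <- train(config$family, Xtr, train_docs$label, cv$best,
                 seed = train_seed)

  say("calibrate", "threshold sweep on %d validation documents", nrow(gold_val))
  p_val <- predict_proba(model, Xval)
  sweep <- threshold_sweep(p_val, gold_val$label)
  thr <- select_threshold(sweep, min_recall = config$min_recall)

  say("evaluate", "threshold %.1f on %d test documents", thr, nrow(gold_test))
  p_test <- predict_proba(model, Xte)
  pred <- p_test >= thr
  cm <- confusion(gold_test$label, pred)
  ms <- compute_metrics(cm)
  ci <- bootstrap_ci(gold_test$label, pred, "f1",
                     iterations = config$bootstrap_iterations,
                     seed = config$seeds$bootstrap %||% 7L)
  baseline <- evaluate_baseline(pools, gold_test,
                                iterations = config$bootstrap_iterations,
                                seed = config$seeds$bootstrap %||% 7L)

  report <- structure(list(
    representation = if (config$family == "ncd_knn") "NCD" else
      toupper(config$representation),
    family = config$family,
    subset = unclass(config$subset),
    seeds = config$seeds,
    lookback_months = config$lookback_months,
    pool_counts = attr(pools, "report"),
    digests = list(corpus = corpus_digest(corpus),
                   gold = digest::digest(gold, algo = "xxhash64")),
    cv = list(best = cv$best, best_index = cv$best_index,
              best_mean_f1 = cv$summary$f1[cv$best_index],
              n_candidates = length(cv$candidates)),
    threshold_table = as.data.frame(sweep),
    threshold = thr,
    confusion = unclass(cm),
    metrics = list(precision = ms$precision, recall = ms$recall,
                   specificity = ms$specificity, f1 = ms$f1),
    f1_ci = list(lower = ci$lower, upper = ci$upper,
                 iterations = ci$iterations),
    baseline = list(confusion = unclass(baseline$confusion),
                    metrics = list(precision = baseline$metrics$precision,
                                   recall = baseline$metrics$recall,
                                   specificity = baseline$metrics$specificity,
                                   f1 = baseline$metrics$f1),
                    f1_ci = list(lower = baseline$ci$lower,
                                 upper = baseline$ci$upper)),
    n_validation = nrow(gold_val), n_test = nrow(gold_test),
    versions = list(notesieve = as.character(utils::packageVersion("notesieve")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "notesieve_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "columns")
  }
  report
}

featurize_splits <- function(config, train_docs, gold_val, gold_test,
                             note_text, train_seed) {
  rp <- config$representation_params
  tr_text <- train_docs$text
  tr_ids <- train_docs$note_id
  val_text <- note_text(gold_val$note_id)
  te_text <- note_text(gold_test$note_id)
  switch(config$representation,
    bow = {
      f <- fit_bow(tr_text, min_df = rp$min_df %||% 2L, doc_ids = tr_ids)
      list(train = f,
           validation = transform_counts(f, val_text, gold_val$note_id),
           test = transform_counts(f, te_text, gold_test$note_id))
    },
    tfidf = {
      f <- fit_tfidf(tr_text, min_df = rp$min_df %||% 2L, doc_ids = tr_ids)
      list(train = f,
           validation = transform_counts(f, val_text, gold_val$note_id),
           test = transform_counts(f, te_text, gold_test$note_id))
    },
    embedding = {
      model <- train_embedding(tr_text, dim = rp$dim %||% 25L,
                               window = rp$window %||% 5L,
                               epochs = rp$epochs %||% 20L,
                               min_count = rp$min_count %||% 2L,
                               infer_epochs = rp$infer_epochs %||% 50L,
                               seed = train_seed, doc_ids = tr_ids)
      list(train = embed_documents(model, tr_text, tr_ids),
           validation = embed_documents(model, val_text, gold_val$note_id),
           test = embed_documents(model, te_text, gold_test$note_id))
    },
    compression = {
      extra <- isTRUE(rp$extra_compression_features)
      list(train = compression_features(tr_text, extra, tr_ids),
           validation = compression_features(val_text, extra, gold_val$note_id),
           test = compression_features(te_text, extra, gold_test$note_id))
    },
    concept = {
      lex <- config$lexicon
      list(train = concept_vectorize(tr_text, lex, doc_ids = tr_ids),
           validation = concept_vectorize(val_text, lex,
                                          doc_ids = gold_val$note_id),
           test = concept_vectorize(te_text, lex, doc_ids = gold_test$note_id))
    })
}

#' @export
print.notesieve_report <- function(x, ...) {
  cat(sprintf("<notesieve_report: %s + %s>\n", x$representation, x$family))
  cat(sprintf("  threshold %.1f | precision %.2f | recall %.2f | specificity %.2f | F1 %.2f (%.2f-%.2f)\n",
              x$threshold, x$metrics$precision, x$metrics$recall,
              x$metrics$specificity, x$metrics$f1, x$f1_ci$lower,
              x$f1_ci$upper))
  cat(sprintf("  baseline F1 %.2f (%.2f-%.2f)\n", x$baseline$metrics$f1,
              x$baseline$f1_ci$lower, x$baseline$f1_ci$upper))
  invisible(x)
}

#' Compare experiment reports
#'
#' The analogue of a representation-by-classifier results table: one row
#' per report with the four test metrics and the F1 bootstrap CI, sorted by
#' F1. All reports must have been evaluated on the same gold set.
#'
#' @param reports list of `notesieve_report` objects (>= 2).
#' @return data.frame sorted by decreasing F1.
#' @export
compare_runs <- function(reports) {
  if (length(reports) < 2L) stop_user("compare_runs needs at least 2 reports")
  golds <- vapply(reports, function(r) r$digests$gold, character(1))
  if (length(unique(golds)) != 1L) {
    stop_user("comparison error: reports evaluate different gold sets")
  }
  rows <- lapply(reports, function(r) {
    data.frame(representation = r$representation, family = r$family,
               precision = r$metrics$precision, recall = r$metrics$recall,
               specificity = r$metrics$specificity, f1 = r$metrics$f1,
               f1_ci_lower = r$f1_ci$lower, f1_ci_upper = r$f1_ci$upper,
               threshold = r$threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$f1), ]
  rownames(out) <- NULL
  out
}
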