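# Fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (explicit loops, dictionaries) and never
# call the package code paths they check.

# --- hand-built timeline fixture ------------------------------------------
# One COPD patient (P1) whose first coded encounter is 2018-06-15, plus one
# never-coded patient (P2). Notes cover all four labeling branches:
#   N1 coded encounter            -> COPD_ENCOUNTER
#   N2 30 months before first dx  -> PRE_COPD
#   N3 exactly 24 months before   -> PRE_COPD (boundary inclusive)
#   N4 12 months before, uncoded  -> EXCLUDED (grey zone)
#   N5 after dx, uncoded          -> EXCLUDED
#   N6 never-coded patient        -> NON_COPD
timeline_fixture <- function() {
  notes <- data.frame(
    note_id = c("N1", "N2", "N3", "N4", "N5", "N6"),
    patient_id = c("P1", "P1", "P1", "P1", "P1", "P2"),
    encounter_id = c("E1", "E2", "E3", "E4", "E5", "E6"),
    date = c("2018-06-15", "2015-12-15", "2016-06-15", "2017-06-15",
             "2019-01-10", "2018-03-01"),
    note_type = "progress note",
    text = c("copd exacerbation with dyspnea", "routine visit",
             "knee pain follow up", "mild cough noted", "post visit check",
             "hypertension follow up"),
    stringsAsFactors = FALSE)
  codes <- data.frame(encounter_id = c("E1", "E6"),
                      code = c("J44.9", "I10"),
                      system = c("ICD10CM", "ICD10CM"),
                      stringsAsFactors = FALSE)
  note_corpus(notes, codes = codes)
}

timeline_expected_pools <- c(N1 = "COPD_ENCOUNTER", N2 = "PRE_COPD",
                             N3 = "PRE_COPD", N4 = "EXCLUDED",
                             N5 = "EXCLUDED", N6 = "NON_COPD")

# --- random corpora for round-trip properties ------------------------------
random_mini_corpus <- function(n_patients = 3, seed = 1) {
  set.seed(seed)
  notes <- list(); codes <- list(); k <- 0
  special <- c("fever ≥ 38°", "SpO2 88%", "plain text note",
               "naïve to therapy")
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%02d", p)
    for (e in seq_len(sample(1:3, 1))) {
      k <- k + 1
      eid <- sprintf("E%03d", k)
      d <- as.Date("2015-01-01") + sample(0:2000, 1)
      for (j in seq_len(sample(1:2, 1))) {
        notes[[length(notes) + 1]] <- data.frame(
          note_id = sprintf("N%03d_%d", k, j), patient_id = pid,
          encounter_id = eid, date = d,
          note_type = sample(c("progress", "discharge"), 1),
          text = sample(special, 1), stringsAsFactors = FALSE)
      }
      if (runif(1) < 0.5) {
        codes[[length(codes) + 1]] <- data.frame(
          encounter_id = eid,
          code = sample(c("J44.9", "491.21", "I10", "E11.9"), 1),
          system = sample(c("ICD10CM", "ICD9CM"), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  note_corpus(do.call(rbind, notes),
              codes = if (length(codes)) do.call(rbind, codes) else NULL)
}

# --- text generators -------------------------------------------------------
random_doc <- function(vocab, len) paste(sample(vocab, len, TRUE), collapse = " ")

two_topic_docs <- function(n_per_topic, len = 60, seed = 1) {
  set.seed(seed)
  va <- sprintf("alpha%02d", 1:30)
  vb <- sprintf("beta%02d", 1:30)
  docs <- c(vapply(seq_len(n_per_topic), function(i) random_doc(va, len), ""),
            vapply(seq_len(n_per_topic), function(i) random_doc(vb, len), ""))
  list(docs = docs, labels = rep(c(TRUE, FALSE), each = n_per_topic))
}

# --- independent oracles ---------------------------------------------------
oracle_tokenize <- function(text) {
  t <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  t[nzchar(t)]
}

oracle_bow <- function(docs, min_df = 1) {
  toks <- lapply(docs, oracle_tokenize)
  df <- list()
  for (t in toks) for (w in unique(t)) {
    df[[w]] <- (if (is.null(df[[w]])) 0 else df[[w]]) + 1
  }
  vocab <- sort(names(df)[unlist(df) >= min_df])
  m <- matrix(0, length(docs), length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_along(toks)) for (w in toks[[i]]) {
    if (w %in% vocab) m[i, w] <- m[i, w] + 1
  }
  m
}

oracle_tfidf <- function(docs, min_df = 1) {
  m <- oracle_bow(docs, min_df)
  n <- length(docs)
  for (j in seq_len(ncol(m))) {
    dfj <- sum(m[, j] > 0)
    m[, j] <- m[, j] * (log((1 + n) / (1 + dfj)) + 1)
  }
  for (i in seq_len(nrow(m))) {
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}

oracle_sweep <- function(prob, gold) {
  out <- NULL
  for (t in seq(0, 1, by = 0.1)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(prob)) {
      pred <- prob[i] >= t
      if (gold[i] && pred) tp <- tp + 1
      if (!gold[i] && pred) fp <- fp + 1
      if (gold[i] && !pred) fn <- fn + 1
      if (!gold[i] && !pred) tn <- tn + 1
    }
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    out <- rbind(out, c(t, tp, fp, fn, tn, pr, rc, sp, f1))
  }
  colnames(out) <- c("threshold", "tp", "fp", "fn", "tn", "precision",
                     "recall", "specificity", "f1")
  out
}

# explicit-loop cross-validation oracle: same folds, same per-fold models
# (refit through the public train/predict API), naive metric bookkeeping
oracle_cv_select <- function(family, X, y, candidates, fold_id, seed) {
  mean_f1 <- mean_rec <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    f1s <- recs <- c()
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f; te <- !tr
      m <- notesieve::train(family,
                            if (is.character(X)) X[tr] else X[tr, , drop = FALSE],
                            y[tr], candidates[[ci]],
                            seed = notesieve:::derive_seed(seed, paste0("fold", f)))
      p <- notesieve::predict_proba(m,
                                    if (is.character(X)) X[te] else X[te, , drop = FALSE])
      pred <- p >= 0.5
      tp <- sum(y[te] & pred); fp <- sum(!y[te] & pred); fn <- sum(y[te] & !pred)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1s <- c(f1s, if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0)
      recs <- c(recs, rc)
    }
    mean_f1[ci] <- mean(f1s); mean_rec[ci] <- mean(recs)
  }
  best <- which(mean_f1 >= max(mean_f1) - 1e-12)
  best[order(-mean_rec[best], best)][1]
}
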