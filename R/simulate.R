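#' Synthetic cohort parameters
#'
#' The stated world of the simulator. Coding noise couples true note
#' relevance to diagnosis coding:
#' \itemize{
#'   \item `miscoding_rate`: probability that a note at a target-coded
#'     encounter is truly irrelevant (contaminates the positive pool);
#'   \item `uncoded_relevant_rate`: probability that a note at an uncoded
#'     encounter is truly relevant (relevant content the heuristics miss —
#'     this is what caps the code-heuristic baseline's recall);
#'   \item `pre_window_contamination`: probability that an uncoded note in
#'     the 0-24 month pre-diagnosis grey zone is truly relevant (early
#'     signs; these notes are excluded from silver pools).
#' }
#' The default noise levels (0.3 / 0.6 / 0.5) put the code-heuristic
#' baseline in a regime of precision near 0.7 and recall near 0.4 on a
#' pool-stratified gold draw. Note text is a two-topic unigram mixture:
#' relevant notes up-weight a respiratory topic drawn from the bundled toy
#' lexicon; irrelevant notes draw mostly from a general synthetic
#' vocabulary.
#'
#' @param n_patients number of patients.
#' @param copd_prevalence fraction of patients who acquire the condition.
#' @param encounters_per_patient length-2 integer range (inclusive).
#' @param study_start,study_end study window dates.
#' @param miscoding_rate,uncoded_relevant_rate,pre_window_contamination
#'   coding-noise probabilities, see above.
#' @param p_code_post probability that a post-diagnosis encounter of a
#'   condition patient carries a target code (the first-diagnosis encounter
#'   always does).
#' @param topic_weight_relevant,topic_weight_irrelevant probability that a
#'   token of a relevant (resp. irrelevant) note is drawn from the
#'   respiratory topic.
#' @param vocab_general size of the general synthetic vocabulary.
#' @param mean_note_length mean tokens per note (Poisson).
#' @param note_types note-type categories sampled uniformly.
#' @param lookback_months grey-zone width used by the generator's branch
#'   bookkeeping; keep equal to the labeling lookback.
#' @param seed integer seed; generation is fully deterministic.
#' @return a list of class `notesieve_cohort_params`.
#' @export
cohort_params <- function(n_patients = 200L, copd_prevalence = 0.5,
                          encounters_per_patient = c(6L, 12L),
                          study_start = "2012-01-01", study_end = "2020-12-31",
                          miscoding_rate = 0.3, uncoded_relevant_rate = 0.6,
                          pre_window_contamination = 0.5, p_code_post = 0.7,
                          topic_weight_relevant = 0.7,
                          topic_weight_irrelevant = 0.05,
                          vocab_general = 400L, mean_note_length = 80,
                          note_types = c("progress note", "discharge summary",
                                         "radiology report"),
                          lookback_months = 24L, seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            copd_prevalence = copd_prevalence,
            encounters_per_patient = as.integer(encounters_per_patient),
            study_start = as.Date(study_start), study_end = as.Date(study_end),
            miscoding_rate = miscoding_rate,
            uncoded_relevant_rate = uncoded_relevant_rate,
            pre_window_contamination = pre_window_contamination,
            p_code_post = p_code_post,
            topic_weight_relevant = topic_weight_relevant,
            topic_weight_irrelevant = topic_weight_irrelevant,
            vocab_general = as.integer(vocab_general),
            mean_note_length = mean_note_length,
            note_types = note_types,
            lookback_months = as.integer(lookback_months),
            seed = as.integer(seed))
  probs <- c(p$copd_prevalence, p$miscoding_rate, p$uncoded_relevant_rate,
             p$pre_window_contamination, p$p_code_post,
             p$topic_weight_relevant, p$topic_weight_irrelevant)
  if (any(probs < 0 | probs > 1)) stop_user("parameter error: probabilities must lie in [0,1]")
  if (length(p$encounters_per_patient) != 2L ||
      p$encounters_per_patient[1] > p$encounters_per_patient[2] ||
      p$encounters_per_patient[1] < 1L) {
    stop_user("parameter error: encounters_per_patient must be a valid range")
  }
  months_span <- as.integer(round(as.numeric(p$study_end - p$study_start) / 30.44))
  if (months_span < p$lookback_months + 12L) {
    stop_user("parameter error: study window (%d months) too short for a %d-month pre-diagnosis span",
              months_span, p$lookback_months)
  }
  structure(p, class = "notesieve_cohort_params")
}

# deterministic pseudo-word list for the general topic
general_vocabulary <- function(n) {
  syl <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "na",
           "pe", "ri", "so", "tu", "va", "we", "xi", "yo", "zu", "qa")
  words <- as.vector(outer(outer(syl, syl, paste0), syl, paste0))
  words[seq_len(min(n, length(words)))]
}

respiratory_vocabulary <- function() {
  lex <- toy_lexicon()
  unique(unlist(tokenize(lex$terms$term)))
}

#' Generate a synthetic EHR cohort with ground truth
#'
#' Emulates an EHR note corpus for exercising the labeling, representation,
#' classification and evaluation modules without any real data: patients
#' with encounter timelines, a first-diagnosis date for condition patients,
#' target-coded encounters thereafter, coding noise per
#' [cohort_params()], and note text drawn from a two-topic unigram mixture
#' conditioned on true relevance. Each note records the silver pool the
#' generator intended it to land in (`branch`), so heuristic output can be
#' checked against construction.
#'
#' @param params a `notesieve_cohort_params`.
#' @return a list of class `notesieve_cohort`: `corpus`
#'   (a `notesieve_corpus`), `truth` (data.frame `note_id`, `relevant`,
#'   `branch`), `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "notesieve_cohort_params"))
  with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  resp_vocab <- respiratory_vocabulary()
  gen_vocab <- general_vocabulary(p$vocab_general)
  # mild Zipf tilt within each topic
  resp_w <- 1 / seq_along(resp_vocab)^0.5
  gen_w <- 1 / seq_along(gen_vocab)^0.5
  codeset <- copd_codeset()
  all_codes <- rbind(data.frame(code = codeset$icd9, system = "ICD9CM"),
                     data.frame(code = codeset$icd10, system = "ICD10CM"))
  noise_codes <- data.frame(code = c("I10", "E11.9", "M54.5", "K21.9", "F41.1"),
                            system = "ICD10CM")
  window_days <- as.numeric(p$study_end - p$study_start)
  # first diagnosis placed to guarantee a non-empty pre-diagnosis pool:
  # at least lookback + 6 months after window start, 6 months before end
  dx_lo <- add_months(p$study_start, p$lookback_months + 6L)
  dx_hi <- add_months(p$study_end, -6L)

  notes <- list(); codes <- list(); encs <- list(); truth <- list()
  n_enc_total <- 0L
  for (i in seq_len(p$n_patients)) {
    pid <- sprintf("P%04d", i)
    is_copd <- runif(1) < p$copd_prevalence
    rng_enc <- p$encounters_per_patient
    n_enc <- if (rng_enc[1] == rng_enc[2]) rng_enc[1] else
      sample(seq(rng_enc[1], rng_enc[2]), 1L)
    dates <- p$study_start + sort(sample.int(window_days + 1L, n_enc,
                                             replace = TRUE) - 1L)
    first_dx <- NULL
    if (is_copd) {
      first_dx <- dx_lo + floor(runif(1) * as.numeric(dx_hi - dx_lo + 1))
      # the first-diagnosis encounter always exists and is coded
      dates[which.min(abs(as.numeric(dates - first_dx)))] <- first_dx
      dates <- sort(dates)
    }
    for (e in seq_len(n_enc)) {
      n_enc_total <- n_enc_total + 1L
      eid <- sprintf("E%06d", n_enc_total)
      d <- dates[e]
      coded <- FALSE
      if (is_copd && d >= first_dx) {
        coded <- (d == first_dx) || (runif(1) < p$p_code_post)
      }
      encs[[n_enc_total]] <- data.frame(encounter_id = eid, patient_id = pid,
                                        date = d, stringsAsFactors = FALSE)
      if (coded) {
        k <- sample(1:2, 1L)
        pick <- all_codes[sample(nrow(all_codes), k), ]
        codes[[length(codes) + 1L]] <- data.frame(encounter_id = eid,
                                                  code = pick$code,
                                                  system = pick$system,
                                                  stringsAsFactors = FALSE)
      }
      if (runif(1) < 0.3) {  # unrelated comorbidity coding either way
        pick <- noise_codes[sample(nrow(noise_codes), 1L), ]
        codes[[length(codes) + 1L]] <- data.frame(encounter_id = eid,
                                                  code = pick$code,
                                                  system = pick$system,
                                                  stringsAsFactors = FALSE)
      }
      # intended silver pool, from construction
      branch <- if (coded) "COPD_ENCOUNTER"
        else if (!is_copd) "NON_COPD"
        else if (d <= add_months(first_dx, -p$lookback_months)) "PRE_COPD"
        else "EXCLUDED"
      grey_zone <- !coded && is_copd &&
        d > add_months(first_dx, -p$lookback_months) && d < first_dx
      relevant <- if (coded) {
        runif(1) >= p$miscoding_rate
      } else if (grey_zone) {
        runif(1) < p$pre_window_contamination
      } else {
        runif(1) < p$uncoded_relevant_rate
      }
      nid <- sprintf("N%06d", n_enc_total)
      len <- max(10L, rpois(1, p$mean_note_length))
      w_resp <- if (relevant) p$topic_weight_relevant else p$topic_weight_irrelevant
      from_resp <- runif(len) < w_resp
      toks <- character(len)
      if (any(from_resp)) {
        toks[from_resp] <- sample(resp_vocab, sum(from_resp), replace = TRUE,
                                  prob = resp_w)
      }
      if (any(!from_resp)) {
        toks[!from_resp] <- sample(gen_vocab, sum(!from_resp), replace = TRUE,
                                   prob = gen_w)
      }
      text <- paste(toks, collapse = " ")
      if (!relevant && runif(1) < 0.2) {
        # irrelevant notes occasionally mention-and-negate a respiratory term
        text <- paste(text, sprintf("no evidence of %s.",
                                    sample(resp_vocab, 1L)))
      }
      notes[[n_enc_total]] <- data.frame(
        note_id = nid, patient_id = pid, encounter_id = eid, date = d,
        note_type = sample(p$note_types, 1L), text = text,
        stringsAsFactors = FALSE)
      truth[[n_enc_total]] <- data.frame(note_id = nid, relevant = relevant,
                                         branch = branch,
                                         stringsAsFactors = FALSE)
    }
  }
  corpus <- note_corpus(do.call(rbind, notes),
                        encounters = do.call(rbind, encs),
                        codes = if (length(codes)) do.call(rbind, codes) else NULL,
                        patients = NULL, codeset = codeset)
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$note_id), ]
  rownames(truth) <- NULL
  structure(list(corpus = corpus, truth = truth, params = p),
            class = "notesieve_cohort")
}

#' @export
print.notesieve_cohort <- function(x, ...) {
  cat(sprintf("<notesieve_cohort: %d notes (%d truly relevant), %d patients, seed %d>\n",
              nrow(x$truth), sum(x$truth$relevant), nrow(x$corpus$patients),
              x$params$seed))
  print(table(x$truth$branch))
  invisible(x)
}

#' Simulate gold annotations from ground truth
#'
#' Stands in for expert annotation: samples `n` notes stratified across the
#' three silver pools in the proportions of the reference 107/100/100 draw
#' (exact at `n = 307`; largest-remainder otherwise) and emits each note's
#' true relevance as its gold label.
#'
#' @param cohort a `notesieve_cohort` (or its `truth` data.frame).
#' @param n number of annotations.
#' @param seed integer seed.
#' @param strata_weights draw weights for pools
#'   COPD_ENCOUNTER / NON_COPD / PRE_COPD.
#' @return data.frame with columns `note_id`, `label`
#'   (`relevant`/`irrelevant`).
#' @export
generate_gold_annotations <- function(cohort, n = 307L, seed = 7L,
                                      strata_weights = c(107, 100, 100)) {
  truth <- if (inherits(cohort, "notesieve_cohort")) cohort$truth else cohort
  stopifnot(all(c("note_id", "relevant", "branch") %in% names(truth)))
  pools3 <- c("COPD_ENCOUNTER", "NON_COPD", "PRE_COPD")
  sizes <- vapply(pools3, function(b) sum(truth$branch == b), integer(1))
  alloc <- allocate_counts(n, strata_weights)
  if (any(alloc > sizes)) {
    stop_user("annotation draw exceeds pool capacity: need %s, have %s",
              paste(alloc, collapse = "/"), paste(sizes, collapse = "/"))
  }
  ids <- with_seed(derive_seed(seed, "gold-annotations"), {
    unlist(lapply(seq_along(pools3), function(k) {
      cand <- truth$note_id[truth$branch == pools3[k]]
      sample(cand, alloc[k])
    }))
  })
  out <- data.frame(note_id = ids,
                    label = ifelse(truth$relevant[match(ids, truth$note_id)],
                                   "relevant", "irrelevant"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a cohort's files to a directory
#'
#' Emits `notes.jsonl` (corpus), `truth.jsonl` (ground truth), and
#' `gold.csv` (simulated annotations).
#'
#' @param cohort a `notesieve_cohort`.
#' @param dir output directory (created if needed).
#' @param gold_n,gold_seed annotation draw settings.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gold_n = 307L, gold_seed = 7L) {
  stopifnot(inherits(cohort, "notesieve_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(cohort$corpus, file.path(dir, "notes.jsonl"))
  con <- file(file.path(dir, "truth.jsonl"), open = "wb")
  for (i in seq_len(nrow(cohort$truth))) {
    writeLines(jsonlite::toJSON(as.list(cohort$truth[i, ]), auto_unbox = TRUE,
                                dataframe = "rows"), con, useBytes = TRUE)
  }
  close(con)
  gold <- generate_gold_annotations(cohort, n = gold_n, seed = gold_seed)
  utils::write.csv(gold, file.path(dir, "gold.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
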