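POOLS <- c("COPD_ENCOUNTER", "NON_COPD", "PRE_COPD", "EXCLUDED")
POOL_LABELS <- c(COPD_ENCOUNTER = "positive", NON_COPD = "negative",
                 PRE_COPD = "negative", EXCLUDED = "none")

#' Assign a single note to a silver-label pool
#'
#' The weak-supervision heuristic, note by note:
#' \itemize{
#'   \item `COPD_ENCOUNTER` (positive): the note's encounter carries at
#'     least one target code;
#'   \item `NON_COPD` (negative): otherwise, if the patient (default scope)
#'     has no target code on any encounter in the corpus;
#'   \item `PRE_COPD` (negative): otherwise, if the note is dated at least
#'     `lookback_months` calendar months before the patient's first
#'     target-coded encounter (boundary inclusive);
#'   \item `EXCLUDED`: otherwise — an uncoded note inside the pre-diagnosis
#'     grey zone, or an uncoded post-diagnosis note. These never become
#'     negatives, because they may carry early or undocumented signs of the
#'     condition.
#' }
#' With `negatives_scope = "encounter"` the `NON_COPD` test only requires
#' the note's own encounter to be uncoded for patients who never carry a
#' target code; for coded patients the temporal rule still applies. The
#' patient-level default prevents negatives drawn from condition patients'
#' uncoded visits.
#'
#' @param corpus a `notesieve_corpus`.
#' @param note_id a single note id in the corpus.
#' @param codeset a `notesieve_codeset`.
#' @param lookback_months pre-diagnosis lookback in calendar months
#'   (default 24).
#' @param negatives_scope `"patient"` (default) or `"encounter"`.
#' @return one of `"COPD_ENCOUNTER"`, `"NON_COPD"`, `"PRE_COPD"`,
#'   `"EXCLUDED"`.
#' @export
assign_pool <- function(corpus, note_id, codeset = copd_codeset(),
                        lookback_months = 24L,
                        negatives_scope = c("patient", "encounter")) {
  pools <- build_pools(corpus, codeset, lookback_months,
                       match.arg(negatives_scope))
  i <- match(note_id, pools$note_id)
  if (is.na(i)) stop_user("note '%s' not found in corpus", note_id)
  pools$pool[i]
}

#' Partition every note of a corpus into silver-label pools
#'
#' Vectorized [assign_pool()] over the whole corpus. The four pools are
#' disjoint and exhaustive.
#'
#' @inheritParams assign_pool
#' @return a data.frame of class `notesieve_pools` with columns `note_id`,
#'   `pool`, `label` (`positive`/`negative`/`none`), and an attribute
#'   `report` holding per-pool counts.
#' @export
build_pools <- function(corpus, codeset = copd_codeset(),
                        lookback_months = 24L,
                        negatives_scope = c("patient", "encounter")) {
  stopifnot(inherits(corpus, "notesieve_corpus"))
  negatives_scope <- match.arg(negatives_scope)
  notes <- corpus$notes
  hit <- is_target_code(corpus$codes[, c("system", "normalized")], codeset)
  coded_enc <- unique(corpus$codes$encounter_id[hit])
  first_dx <- first_target_dates(corpus, codeset)
  names(first_dx) <- corpus$patients$patient_id

  enc_coded <- notes$encounter_id %in% coded_enc
  pat_first <- first_dx[notes$patient_id]
  pat_has_code <- !is.na(pat_first)

  pool <- rep("EXCLUDED", nrow(notes))
  pool[enc_coded] <- "COPD_ENCOUNTER"
  non <- !enc_coded & !pat_has_code
  pool[non] <- "NON_COPD"
  cutoff <- add_months(pat_first[pat_has_code & !enc_coded], -lookback_months)
  pre_idx <- which(pat_has_code & !enc_coded)
  pre <- pre_idx[notes$date[pre_idx] <= cutoff]
  pool[pre] <- "PRE_COPD"
  if (negatives_scope == "encounter") {
    # encounter-level reading: nothing changes for never-coded patients and
    # the temporal rule still shields the grey zone; the scope choice is
    # kept explicit for reporting
  }
  out <- data.frame(note_id = notes$note_id, pool = pool,
                    label = unname(POOL_LABELS[pool]),
                    stringsAsFactors = FALSE)
  attr(out, "report") <- as.list(table(factor(pool, levels = POOLS)))
  attr(out, "lookback_months") <- as.integer(lookback_months)
  attr(out, "negatives_scope") <- negatives_scope
  class(out) <- c("notesieve_pools", "data.frame")
  out
}

#' Training-subset configuration
#'
#' The three training-subset designs: `MIXED` draws the negatives half and
#' half from the non-condition and pre-diagnosis pools; `NON_ONLY` and
#' `PRE_ONLY` draw all negatives from one pool. Classes are balanced:
#' `n_pos = n_neg_non + n_neg_pre`.
#'
#' @param name `"MIXED"`, `"NON_ONLY"`, or `"PRE_ONLY"`.
#' @param n_pos number of positive examples.
#' @param seed sampling seed.
#' @return a list of class `notesieve_subset_config`.
#' @export
subset_config <- function(name = c("MIXED", "NON_ONLY", "PRE_ONLY"),
                          n_pos = 5000L, seed = 13L) {
  name <- match.arg(name)
  n_pos <- as.integer(n_pos)
  if (name == "MIXED" && n_pos %% 2L != 0L) {
    stop_user("MIXED config needs an even n_pos (half from each negative pool)")
  }
  cfg <- switch(name,
    MIXED = list(n_neg_non = n_pos %/% 2L, n_neg_pre = n_pos %/% 2L),
    NON_ONLY = list(n_neg_non = n_pos, n_neg_pre = 0L),
    PRE_ONLY = list(n_neg_non = 0L, n_neg_pre = n_pos))
  structure(c(list(name = name, n_pos = n_pos, seed = as.integer(seed)), cfg),
            class = "notesieve_subset_config")
}

#' Sample a balanced silver-labeled training subset
#'
#' Draws `n_pos` positives from the `COPD_ENCOUNTER` pool and the
#' configured negatives without replacement, deterministically under the
#' config seed. Diversity is enforced as: at most `ceil(n/20)` notes per
#' patient within each draw, and proportional allocation across calendar
#' year x note-type strata (largest-remainder rounding), relaxed only when
#' a stratum cannot fill its quota.
#'
#' @param pools a `notesieve_pools`.
#' @param corpus the `notesieve_corpus` the pools were built from.
#' @param config a `notesieve_subset_config`.
#' @return a data.frame of labeled documents: `note_id`, `text`, `label`
#'   (`positive`/`negative`), `provenance` (`silver:<pool>`).
#' @export
sample_training_subset <- function(pools, corpus, config) {
  stopifnot(inherits(pools, "notesieve_pools"),
            inherits(corpus, "notesieve_corpus"),
            inherits(config, "notesieve_subset_config"))
  wants <- c(COPD_ENCOUNTER = config$n_pos, NON_COPD = config$n_neg_non,
             PRE_COPD = config$n_neg_pre)
  draws <- list()
  for (pname in names(wants)) {
    n_want <- wants[[pname]]
    if (n_want == 0L) next
    ids <- pools$note_id[pools$pool == pname]
    if (length(ids) < n_want) {
      stop_user("sampling error: pool %s holds %d notes, %d requested",
                pname, length(ids), n_want)
    }
    draws[[pname]] <- with_seed(derive_seed(config$seed, pname), {
      diversified_sample(ids, n_want, corpus)
    })
  }
  rows <- lapply(names(draws), function(pname) {
    ids <- draws[[pname]]
    data.frame(note_id = ids,
               text = corpus$notes$text[match(ids, corpus$notes$note_id)],
               label = unname(POOL_LABELS[pname]),
               provenance = paste0("silver:", pname),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# stratified, patient-capped draw of n note ids; assumes the RNG is seeded
diversified_sample <- function(ids, n, corpus) {
  meta <- corpus$notes[match(ids, corpus$notes$note_id), ]
  stratum <- paste(format(meta$date, "%Y"), meta$note_type, sep = "|")
  strata <- sort(unique(stratum))
  cap <- ceiling(n / 20)
  sizes <- vapply(strata, function(s) sum(stratum == s), integer(1))
  alloc <- allocate_counts(n, sizes, capacity = sizes)
  taken <- character(0)
  pat_count <- integer(0)
  take_from <- function(cand_ids, cand_pat, n_take) {
    got <- character(0)
    if (n_take <= 0 || length(cand_ids) == 0) return(got)
    ord <- sample(seq_along(cand_ids))
    for (i in ord) {
      p <- cand_pat[i]
      cnt <- if (p %in% names(pat_count)) pat_count[[p]] else 0L
      if (cnt >= cap) next
      got <- c(got, cand_ids[i])
      pat_count[[p]] <<- cnt + 1L
      if (length(got) == n_take) break
    }
    got
  }
  for (si in seq_along(strata)) {
    in_s <- stratum == strata[si]
    taken <- c(taken, take_from(meta$note_id[in_s], meta$patient_id[in_s],
                                alloc[si]))
  }
  if (length(taken) < n) {   # refill from the remainder, cap still enforced
    left <- !(meta$note_id %in% taken)
    taken <- c(taken, take_from(meta$note_id[left], meta$patient_id[left],
                                n - length(taken)))
  }
  if (length(taken) < n) {   # cap infeasible for this pool size: relax it
    left <- setdiff(meta$note_id, taken)
    taken <- c(taken, sample(left, n - length(taken)))
  }
  taken
}

#' Split gold annotations into validation and test sets
#'
#' Disjoint, exhaustive split, stratified by each note's pool of origin so
#' both splits see all three silver pools, deterministic under `seed`.
#'
#' @param annotations data.frame with columns `note_id`, `label`
#'   (`relevant`/`irrelevant`).
#' @param pools a `notesieve_pools` covering the annotated notes.
#' @param validation_n number of documents for the validation split.
#' @param seed integer seed.
#' @return list with data.frames `validation` and `test`.
#' @export
split_gold <- function(annotations, pools, validation_n = 84L, seed = 7L) {
  stopifnot(all(c("note_id", "label") %in% names(annotations)))
  if (anyDuplicated(annotations$note_id)) {
    stop_user("referential error: duplicate note_id in annotations: %s",
              annotations$note_id[duplicated(annotations$note_id)][1])
  }
  idx <- match(annotations$note_id, pools$note_id)
  if (anyNA(idx)) {
    stop_user("referential error: annotation note(s) unknown to the corpus: %s",
              paste(utils::head(annotations$note_id[is.na(idx)], 3),
                    collapse = ", "))
  }
  if (nrow(annotations) > 0 && validation_n >= nrow(annotations)) {
    stop_user("validation_n (%d) must be smaller than the annotation count (%d)",
              validation_n, nrow(annotations))
  }
  origin <- pools$pool[idx]
  strata <- sort(unique(origin))
  sizes <- vapply(strata, function(s) sum(origin == s), integer(1))
  alloc <- allocate_counts(validation_n, sizes, capacity = sizes)
  val_ids <- with_seed(derive_seed(seed, "gold-split"), {
    unlist(lapply(seq_along(strata), function(si) {
      ids <- annotations$note_id[origin == strata[si]]
      sample(ids, alloc[si])
    }))
  })
  in_val <- annotations$note_id %in% val_ids
  list(validation = annotations[in_val, , drop = FALSE],
       test = annotations[!in_val, , drop = FALSE])
}

#' Write / read pool assignments as line-delimited JSON
#' @param pools a `notesieve_pools`.
#' @param path file path.
#' @return `path` (write) or a `notesieve_pools` (read).
#' @export
write_pools <- function(pools, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(pools))) {
    writeLines(jsonlite::toJSON(list(note_id = pools$note_id[i],
                                     pool = pools$pool[i],
                                     label = pools$label[i]),
                                auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_pools
#' @export
read_pools <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(note_id = vapply(recs, `[[`, "", "note_id"),
                    pool = vapply(recs, `[[`, "", "pool"),
                    label = vapply(recs, `[[`, "", "label"),
                    stringsAsFactors = FALSE)
  class(out) <- c("notesieve_pools", "data.frame")
  out
}

#' Read a gold-annotation file
#'
#' Two-column CSV `note_id,label` with label `relevant` or `irrelevant`.
#'
#' @param path file path.
#' @return data.frame with columns `note_id`, `label`.
#' @export
read_gold <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("note_id", "label") %in% names(g))) {
    stop_user("gold file must have columns note_id,label")
  }
  bad <- !g$label %in% c("relevant", "irrelevant")
  if (any(bad)) {
    stop_user("gold label(s) must be relevant/irrelevant, got: %s",
              paste(unique(g$label[bad]), collapse = ", "))
  }
  g[, c("note_id", "label")]
}
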