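#' Construct a clinical note corpus
#'
#' The corpus is the package's central container: notes with free text,
#' the encounters they belong to, diagnosis codes attached to encounters,
#' and patients. Components are plain data.frames, canonically ordered so
#' that write/read round-trips are exact.
#'
#' @param notes data.frame with columns `note_id`, `patient_id`,
#'   `encounter_id`, `date` (Date or "YYYY-MM-DD"), `note_type`, `text`.
#'   A note's date defaults to its encounter's date; a differing value is an
#'   explicit override (e.g. a discharge summary filed after the visit).
#' @param encounters data.frame with columns `encounter_id`, `patient_id`,
#'   `date`. If omitted, derived from `notes`.
#' @param codes data.frame with columns `encounter_id`, `code`, `system`.
#'   Optional.
#' @param patients data.frame with columns `patient_id` and optionally
#'   `birth_date`. If omitted, derived from `encounters`.
#' @param codeset a `notesieve_codeset` used to derive each patient's first
#'   condition-coded encounter date (`first_copd_date`).
#' @return an object of class `notesieve_corpus`: a list with data.frames
#'   `notes`, `encounters`, `codes`, `patients`.
#' @export
note_corpus <- function(notes, encounters = NULL, codes = NULL,
                        patients = NULL, codeset = copd_codeset()) {
  req <- c("note_id", "patient_id", "encounter_id", "date", "note_type", "text")
  if (nrow(notes) > 0 && !all(req %in% names(notes))) {
    stop_user("notes lack required column(s): %s",
              paste(setdiff(req, names(notes)), collapse = ", "))
  }
  if (nrow(notes) == 0) {
    notes <- data.frame(note_id = character(), patient_id = character(),
                        encounter_id = character(), date = as.Date(character()),
                        note_type = character(), text = character(),
                        stringsAsFactors = FALSE)
  }
  notes$date <- as_date_strict(notes$date, "note date")
  if (anyDuplicated(notes$note_id)) {
    stop_user("duplicate note_id in corpus: %s",
              notes$note_id[duplicated(notes$note_id)][1])
  }
  if (is.null(encounters)) {
    first <- !duplicated(notes$encounter_id)
    encounters <- data.frame(encounter_id = notes$encounter_id[first],
                             patient_id = notes$patient_id[first],
                             date = notes$date[first],
                             stringsAsFactors = FALSE)
  }
  encounters$date <- as_date_strict(encounters$date, "encounter date")
  if (anyDuplicated(encounters$encounter_id)) {
    stop_user("duplicate encounter_id: %s",
              encounters$encounter_id[duplicated(encounters$encounter_id)][1])
  }
  dangling <- setdiff(notes$encounter_id, encounters$encounter_id)
  if (length(dangling)) {
    stop_user("referential integrity: note(s) reference missing encounter(s): %s",
              paste(utils::head(dangling, 3), collapse = ", "))
  }
  if (is.null(codes) || nrow(codes) == 0) {
    codes <- data.frame(encounter_id = character(), code = character(),
                        system = character(), stringsAsFactors = FALSE)
  } else {
    bad <- setdiff(codes$encounter_id, encounters$encounter_id)
    if (length(bad)) {
      stop_user("referential integrity: code(s) reference missing encounter(s): %s",
                paste(utils::head(bad, 3), collapse = ", "))
    }
    norm <- normalize_code(codes$code, codes$system)
    codes <- data.frame(encounter_id = codes$encounter_id, code = norm$raw,
                        system = norm$system, normalized = norm$normalized,
                        stringsAsFactors = FALSE)
  }
  if (!"normalized" %in% names(codes)) codes$normalized <- character()
  if (is.null(patients)) {
    first <- !duplicated(encounters$patient_id)
    patients <- data.frame(patient_id = encounters$patient_id[first],
                           stringsAsFactors = FALSE)
  }
  if (!"birth_date" %in% names(patients)) {
    patients$birth_date <- rep(as.Date(NA), nrow(patients))
  } else {
    patients$birth_date <- as_date_strict(patients$birth_date, "birth date")
  }
  badp <- setdiff(notes$patient_id, patients$patient_id)
  if (length(badp)) {
    stop_user("referential integrity: note(s) reference missing patient(s): %s",
              paste(utils::head(badp, 3), collapse = ", "))
  }
  # canonical ordering makes round-trips and digests stable
  notes <- notes[order(notes$patient_id, notes$date, notes$note_id),
                 req, drop = FALSE]
  encounters <- encounters[order(encounters$encounter_id),
                           c("encounter_id", "patient_id", "date"), drop = FALSE]
  codes <- codes[order(codes$encounter_id, codes$system, codes$normalized),
                 c("encounter_id", "code", "system", "normalized"), drop = FALSE]
  patients <- patients[order(patients$patient_id),
                       c("patient_id", "birth_date"), drop = FALSE]
  rownames(notes) <- rownames(encounters) <- rownames(codes) <-
    rownames(patients) <- NULL
  corpus <- structure(list(notes = notes, encounters = encounters,
                           codes = codes, patients = patients),
                      class = "notesieve_corpus")
  corpus$patients$first_copd_date <- first_target_dates(corpus, codeset)
  corpus
}

#' @export
print.notesieve_corpus <- function(x, ...) {
  cat(sprintf("<notesieve_corpus: %d notes, %d encounters, %d patients, %d codes>\n",
              nrow(x$notes), nrow(x$encounters), nrow(x$patients), nrow(x$codes)))
  invisible(x)
}

#' First condition-coded encounter date per patient
#'
#' For each patient, the minimum encounter date over encounters carrying at
#' least one code in `codeset`; `NA` for patients with none.
#'
#' @param corpus a `notesieve_corpus`.
#' @param codeset a `notesieve_codeset`.
#' @return Date vector aligned with `corpus$patients`.
#' @export
first_target_dates <- function(corpus, codeset = copd_codeset()) {
  stopifnot(inherits(corpus, "notesieve_corpus"))
  out <- rep(as.Date(NA), nrow(corpus$patients))
  if (nrow(corpus$codes) == 0) return(out)
  hit <- is_target_code(corpus$codes[, c("system", "normalized")], codeset)
  if (!any(hit)) return(out)
  enc_hit <- unique(corpus$codes$encounter_id[hit])
  enc <- corpus$encounters[corpus$encounters$encounter_id %in% enc_hit, ]
  agg <- tapply(enc$date, enc$patient_id, min)
  idx <- match(names(agg), corpus$patients$patient_id)
  out[idx] <- as.Date(as.numeric(agg), origin = "1970-01-01")
  out
}

#' Read a note corpus from line-delimited JSON
#'
#' One JSON object per line with keys `note_id`, `patient_id`,
#' `encounter_id`, `date` (ISO-8601), `note_type`, `text`, `codes` (array of
#' `{code, system}` objects attached to the note's encounter), and optional
#' `birth_date`. The schema is denormalized for streamability: encounter and
#' patient fields ride along on every note line.
#'
#' @param path file path.
#' @param codeset a `notesieve_codeset` for the derived first-diagnosis date.
#' @return a `notesieve_corpus`.
#' @export
read_corpus <- function(path, codeset = copd_codeset()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(note_corpus(data.frame(), codeset = codeset))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop_user("parse error at line %d: %s", i,
                                    conditionMessage(e)))
    miss <- setdiff(c("note_id", "patient_id", "encounter_id", "date",
                      "note_type", "text"), names(recs[[i]]))
    if (length(miss)) {
      stop_user("parse error at line %d: missing key(s) %s", i,
                paste(miss, collapse = ", "))
    }
  }
  gets <- function(key, default = NA_character_) {
    vapply(recs, function(r) {
      v <- r[[key]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  notes <- data.frame(note_id = gets("note_id"), patient_id = gets("patient_id"),
                      encounter_id = gets("encounter_id"), date = gets("date"),
                      note_type = gets("note_type"), text = gets("text"),
                      stringsAsFactors = FALSE)
  # encounter fields come from the first line mentioning the encounter;
  # later lines must agree
  enc_first <- !duplicated(notes$encounter_id)
  encounters <- data.frame(encounter_id = notes$encounter_id[enc_first],
                           patient_id = notes$patient_id[enc_first],
                           date = notes$date[enc_first], stringsAsFactors = FALSE)
  enc_pat <- tapply(notes$patient_id, notes$encounter_id,
                    function(p) length(unique(p)))
  if (any(enc_pat > 1)) {
    stop_user("referential integrity: encounter %s appears under multiple patients",
              names(enc_pat)[enc_pat > 1][1])
  }
  code_rows <- list()
  seen_enc <- character()
  for (i in seq_along(recs)) {
    eid <- as.character(recs[[i]]$encounter_id)
    if (eid %in% seen_enc) next
    seen_enc <- c(seen_enc, eid)
    cl <- recs[[i]]$codes
    if (length(cl)) {
      code_rows[[length(code_rows) + 1L]] <- data.frame(
        encounter_id = eid,
        code = vapply(cl, function(c) as.character(c$code), character(1)),
        system = vapply(cl, function(c) as.character(c$system), character(1)),
        stringsAsFactors = FALSE)
    }
  }
  codes <- if (length(code_rows)) do.call(rbind, code_rows) else NULL
  bd <- vapply(recs, function(r) {
    v <- r[["birth_date"]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  pat_first <- !duplicated(notes$patient_id)
  patients <- data.frame(patient_id = notes$patient_id[pat_first],
                         birth_date = bd[pat_first], stringsAsFactors = FALSE)
  note_corpus(notes, encounters = encounters, codes = codes,
              patients = patients, codeset = codeset)
}

#' Write a note corpus as line-delimited JSON
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c))` reproduces `c`
#' field for field.
#'
#' @param corpus a `notesieve_corpus`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "notesieve_corpus"))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_user("cannot write '%s': %s", path,
                                                conditionMessage(e)))
  on.exit(close(con))
  notes <- corpus$notes
  codes_by_enc <- split(corpus$codes[, c("code", "system")],
                        corpus$codes$encounter_id)
  bd <- corpus$patients$birth_date[match(notes$patient_id,
                                         corpus$patients$patient_id)]
  for (i in seq_len(nrow(notes))) {
    rec <- list(note_id = notes$note_id[i], patient_id = notes$patient_id[i],
                encounter_id = notes$encounter_id[i],
                date = format(notes$date[i]), note_type = notes$note_type[i],
                text = notes$text[i])
    cd <- codes_by_enc[[notes$encounter_id[i]]]
    rec$codes <- if (is.null(cd) || nrow(cd) == 0) list() else
      lapply(seq_len(nrow(cd)),
             function(j) list(code = cd$code[j], system = cd$system[j]))
    if (!is.na(bd[i])) rec$birth_date <- format(bd[i])
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

# stable content digest used in run manifests and report comparison
corpus_digest <- function(corpus) {
  digest::digest(lapply(unclass(corpus), function(df) {
    df[] <- lapply(df, as.character)
    df
  }), algo = "xxhash64")
}
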