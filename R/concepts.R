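#' Concept lexicons
#'
#' A concept lexicon maps surface terms (possibly multi-token) to stable
#' concept identifiers, CUI-style, plus a list of negation trigger phrases.
#' It is a deliberately generic stand-in for a full terminology server: the
#' package ships a small synthetic respiratory lexicon as a fixture
#' (`system.file("extdata", "respiratory_lexicon.tsv", package = "notesieve")`).
#'
#' @param terms data.frame with columns `term`, `concept_id`.
#' @param triggers character vector of negation trigger phrases.
#' @return an object of class `notesieve_lexicon`.
#' @export
concept_lexicon <- function(terms, triggers = default_negation_triggers()) {
  stopifnot(is.data.frame(terms), all(c("term", "concept_id") %in% names(terms)))
  terms$term <- tolower(trimws(terms$term))
  terms$concept_id <- as.character(terms$concept_id)
  terms <- terms[nzchar(terms$term), c("term", "concept_id")]
  terms <- terms[!duplicated(terms$term), ]
  term_tokens <- tokenize(terms$term)
  if (is.character(term_tokens)) term_tokens <- list(term_tokens)
  structure(list(terms = terms,
                 term_tokens = term_tokens,
                 term_keys = vapply(term_tokens, paste, character(1),
                                    collapse = " "),
                 max_ngram = max(c(1L, lengths(term_tokens))),
                 triggers = tolower(trimws(triggers)),
                 concept_ids = sort(unique(terms$concept_id))),
            class = "notesieve_lexicon")
}

#' @export
print.notesieve_lexicon <- function(x, ...) {
  cat(sprintf("<notesieve_lexicon: %d terms, %d concepts, %d negation triggers>\n",
              nrow(x$terms), length(x$concept_ids), length(x$triggers)))
  invisible(x)
}

#' Read a concept lexicon from TSV
#'
#' @param path TSV with columns `term`, `concept_id` (header required).
#' @param triggers_path optional file with one negation trigger phrase per
#'   line; defaults to the built-in trigger list.
#' @return a `notesieve_lexicon`.
#' @export
read_lexicon <- function(path, triggers_path = NULL) {
  terms <- utils::read.delim(path, stringsAsFactors = FALSE)
  trig <- if (is.null(triggers_path)) default_negation_triggers() else {
    t <- readLines(triggers_path, encoding = "UTF-8", warn = FALSE)
    t[nzchar(trimws(t))]
  }
  concept_lexicon(terms, trig)
}

#' Built-in negation trigger phrases
#'
#' A NegEx-style list of phrases that, occurring within the 6 tokens before
#' a concept mention in the same sentence, flip its assertion to negated.
#'
#' @return character vector.
#' @export
default_negation_triggers <- function() {
  c("no", "not", "without", "denies", "denied", "negative for",
    "no evidence of", "no signs of", "free of", "rules out", "ruled out",
    "absence of", "never")
}

#' Bundled synthetic respiratory lexicon
#'
#' Loads the toy 40-term lexicon shipped with the package. The terms are
#' respiratory vocabulary; most identifiers are synthetic placeholders in
#' CUI format (only well-known anchors such as C0018787 for "heart" are
#' real).
#'
#' @return a `notesieve_lexicon`.
#' @export
toy_lexicon <- function() {
  read_lexicon(system.file("extdata", "respiratory_lexicon.tsv",
                           package = "notesieve", mustWork = TRUE),
               system.file("extdata", "negation_triggers.txt",
                           package = "notesieve", mustWork = TRUE))
}

#' Extract concept mentions with assertion status
#'
#' Greedy longest-match lookup of lexicon terms over token n-grams
#' (n up to the longest lexicon term, capped at 5), case-insensitive.
#' A mention is negated (assertion -1) if a negation trigger occurs within
#' the 6 tokens preceding it inside the same sentence (sentences bounded by
#' `.`, `!`, `?`, newline); otherwise affirmed (+1).
#'
#' @param text a single string.
#' @param lexicon a `notesieve_lexicon`.
#' @return data.frame with columns `concept_id`, `assertion` (+1/-1),
#'   `term`, `start`, `end` (character offsets).
#' @examples
#' lex <- concept_lexicon(data.frame(term = "heart", concept_id = "C0018787"))
#' extract_concepts("the heart is enlarged", lex)
#' @export
extract_concepts <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "notesieve_lexicon"))
  sp <- tokenize_spans(text)
  n <- nrow(sp)
  empty <- data.frame(concept_id = character(), assertion = integer(),
                      term = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  max_n <- min(lexicon$max_ngram, 5L)
  # trigger phrases as token sequences
  trig_tokens <- tokenize(lexicon$triggers)
  if (is.character(trig_tokens)) trig_tokens <- list(trig_tokens)
  hits <- list()
  i <- 1L
  while (i <= n) {
    matched <- 0L
    concept <- NA_character_
    term <- NA_character_
    for (len in rev(seq_len(min(max_n, n - i + 1L)))) {
      j <- i + len - 1L
      if (sp$sentence[j] != sp$sentence[i]) next
      key <- paste(sp$token[i:j], collapse = " ")
      hit <- match(key, lexicon$term_keys)
      if (!is.na(hit)) {
        matched <- len
        concept <- lexicon$terms$concept_id[hit]
        term <- lexicon$terms$term[hit]
        break
      }
    }
    if (matched > 0L) {
      # negation: any trigger token-sequence ending within the 6 tokens
      # before position i, same sentence
      neg <- FALSE
      lo <- max(1L, i - 6L)
      win <- seq.int(lo, i - 1L)
      win <- win[sp$sentence[win] == sp$sentence[i]]
      if (length(win)) {
        for (tt in trig_tokens) {
          L <- length(tt)
          for (e in win) {
            s <- e - L + 1L
            if (s < 1L || sp$sentence[s] != sp$sentence[i]) next
            if (identical(sp$token[s:e], tt)) { neg <- TRUE; break }
          }
          if (neg) break
        }
      }
      hits[[length(hits) + 1L]] <- data.frame(
        concept_id = concept, assertion = if (neg) -1L else 1L,
        term = term, start = sp$start[i], end = sp$end[i + matched - 1L],
        stringsAsFactors = FALSE)
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  if (length(hits) == 0) return(empty)
  do.call(rbind, hits)
}

#' Concept-vector features
#'
#' One column per concept identifier in the lexicon. Cell values encode
#' presence with assertion status: +1 if the concept is affirmed at least
#' once in the document (affirmation dominates over co-occurring negations),
#' -1 if it is only ever negated, 0 if absent. Set
#' `negation_dominates = TRUE` to let a single negation win instead.
#'
#' @param docs character vector of texts.
#' @param lexicon a `notesieve_lexicon`.
#' @param negation_dominates conflict rule flip (default `FALSE`).
#' @param doc_ids optional row ids.
#' @return a `notesieve_features` with tag `"CONCEPT"` (dense matrix with
#'   values in -1/0/+1).
#' @export
concept_vectorize <- function(docs, lexicon, negation_dominates = FALSE,
                              doc_ids = NULL) {
  stopifnot(inherits(lexicon, "notesieve_lexicon"))
  cids <- lexicon$concept_ids
  n <- length(docs)
  ids <- doc_ids %||% names(docs) %||% sprintf("doc%d", seq_len(n))
  m <- matrix(0, nrow = n, ncol = length(cids),
              dimnames = list(ids, cids))
  for (d in seq_len(n)) {
    ex <- extract_concepts(docs[d], lexicon)
    if (nrow(ex) == 0) next
    for (cid in unique(ex$concept_id)) {
      a <- ex$assertion[ex$concept_id == cid]
      affirmed <- any(a > 0)
      negated <- any(a < 0)
      v <- if (negation_dominates) {
        if (negated) -1 else 1
      } else {
        if (affirmed) 1 else -1
      }
      m[d, cid] <- v
    }
  }
  vocab <- data.frame(token = cids, index = seq_along(cids), df = NA_integer_,
                      stringsAsFactors = FALSE)
  new_features(m, vocab, "CONCEPT")
}
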