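#' Tokenize clinical text
#'
#' Lowercases and extracts maximal runs of ASCII letters and digits, in
#' order. Deliberately simple — no stemming, no stop-word removal — so every
#' representation sees the same token stream.
#'
#' @param text character vector.
#' @return for a single string, a character vector of tokens; for a vector,
#'   a list of such vectors.
#' @examples
#' tokenize("COPD exacerbation, SpO2 88%")
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(list())
  text <- tolower(as.character(text))
  m <- gregexpr("[a-z0-9]+", text, perl = TRUE)
  toks <- regmatches(text, m)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (length(text) == 1L) toks[[1]] else toks
}

# Tokenize one string keeping token positions and sentence ids.
# Sentences are bounded by '.', '!', '?' or newline; used by the negation
# window in concept extraction.
tokenize_spans <- function(text) {
  text <- as.character(text)
  if (!nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  low <- tolower(text)
  m <- gregexpr("[a-z0-9]+", low, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(low, starts, starts + lens - 1L)
  # sentence id = number of boundary characters before the token start
  bnd <- gregexpr("[.!?\n]", low, perl = TRUE)[[1]]
  bnd <- if (bnd[1] == -1) integer() else as.integer(bnd)
  sentence <- findInterval(starts, bnd) + 1L
  data.frame(token = tokens, start = starts, end = starts + lens - 1L,
             sentence = sentence, stringsAsFactors = FALSE)
}
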