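#' Bag-of-words features
#'
#' Fits a vocabulary on the documents (tokens with document frequency
#' below `min_df` dropped) and returns raw term counts as a sparse
#' documents-by-terms matrix.
#'
#' @param docs character vector of document texts, or a list of pre-tokenized
#'   documents. Names (or a `doc_ids` argument) become row ids.
#' @param min_df minimum document frequency for a token to enter the
#'   vocabulary.
#' @param doc_ids optional character vector of row ids.
#' @return a list of class `notesieve_features` with elements `matrix`
#'   (dgCMatrix), `vocabulary` (data.frame `token`, `index`, `df`, and for
#'   TF-IDF `idf`), and `representation` tag.
#' @export
fit_bow <- function(docs, min_df = 1L, doc_ids = NULL) {
  counts_features(docs, min_df, doc_ids, tfidf = FALSE)
}

#' TF-IDF features
#'
#' Term frequency times smoothed inverse document frequency,
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, with rows L2-normalized —
#' the common modern default. A token present in every document gets the
#' minimal weight `idf = 1`.
#'
#' @inheritParams fit_bow
#' @param l2_normalize normalize each row to unit Euclidean norm
#'   (default `TRUE`).
#' @return see [fit_bow()].
#' @export
fit_tfidf <- function(docs, min_df = 1L, doc_ids = NULL, l2_normalize = TRUE) {
  counts_features(docs, min_df, doc_ids, tfidf = TRUE, l2 = l2_normalize)
}

counts_features <- function(docs, min_df, doc_ids, tfidf, l2 = TRUE) {
  toks <- if (is.list(docs) && !is.character(docs)) docs else {
    t <- tokenize(docs)
    if (is.character(t)) list(t) else t
  }
  n <- length(toks)
  if (n == 0) stop_user("no documents supplied")
  ids <- doc_ids %||% names(toks) %||% sprintf("doc%d", seq_len(n))
  # document frequency over unique tokens per doc
  uniq <- lapply(toks, unique)
  df_tab <- table(unlist(uniq))
  keep <- names(df_tab)[df_tab >= min_df]
  if (length(keep) == 0) stop_user("empty vocabulary: no token reaches min_df=%d", min_df)
  vocab <- sort(keep)
  vidx <- stats::setNames(seq_along(vocab), vocab)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (d in seq_len(n)) {
    t <- toks[[d]]
    t <- t[t %in% vocab]
    if (length(t) == 0) next
    tc <- table(t)
    ii <- c(ii, rep.int(d, length(tc)))
    jj <- c(jj, vidx[names(tc)])
    xx <- c(xx, as.numeric(tc))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  vdf <- as.integer(df_tab[vocab])
  vocab_df <- data.frame(token = vocab, index = seq_along(vocab), df = vdf,
                         stringsAsFactors = FALSE)
  rep_tag <- "BOW"
  if (tfidf) {
    idf <- log((1 + n) / (1 + vdf)) + 1
    vocab_df$idf <- idf
    m <- m %*% Matrix::Diagonal(x = idf)
    dimnames(m) <- list(ids, vocab)
    if (l2) m <- l2_norm_rows(m)
    rep_tag <- "TFIDF"
  }
  new_features(m, vocab_df, rep_tag, l2 = if (tfidf) l2 else FALSE)
}

l2_norm_rows <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  dn <- dimnames(m)
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  dimnames(m) <- dn
  m
}

new_features <- function(matrix, vocabulary, representation, ...) {
  structure(list(matrix = matrix, vocabulary = vocabulary,
                 representation = representation, extra = list(...)),
            class = "notesieve_features")
}

#' @export
print.notesieve_features <- function(x, ...) {
  cat(sprintf("<notesieve_features [%s]: %d docs x %d features>\n",
              x$representation, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Project new documents into a fitted vocabulary
#'
#' Applies a fitted bag-of-words or TF-IDF vocabulary (including its stored
#' idf weights and normalization choice) to unseen documents.
#' Out-of-vocabulary tokens are ignored.
#'
#' @param features a `notesieve_features` from [fit_bow()] or [fit_tfidf()].
#' @param docs character vector of texts.
#' @param doc_ids optional row ids.
#' @return a `notesieve_features` over the same columns.
#' @export
transform_counts <- function(features, docs, doc_ids = NULL) {
  stopifnot(inherits(features, "notesieve_features"),
            features$representation %in% c("BOW", "TFIDF"))
  vocab <- features$vocabulary$token
  vidx <- stats::setNames(features$vocabulary$index, vocab)
  toks <- tokenize(docs)
  if (is.character(toks)) toks <- list(toks)
  n <- length(toks)
  ids <- doc_ids %||% names(docs) %||% sprintf("doc%d", seq_len(n))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (d in seq_len(n)) {
    t <- toks[[d]]
    t <- t[t %in% vocab]
    if (length(t) == 0) next
    tc <- table(t)
    ii <- c(ii, rep.int(d, length(tc)))
    jj <- c(jj, vidx[names(tc)])
    xx <- c(xx, as.numeric(tc))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  if (features$representation == "TFIDF") {
    m <- m %*% Matrix::Diagonal(x = features$vocabulary$idf)
    dimnames(m) <- list(ids, vocab)
    if (isTRUE(features$extra$l2)) m <- l2_norm_rows(m)
  }
  new_features(m, features$vocabulary, features$representation,
               l2 = features$extra$l2 %||% FALSE)
}

#' Persist a feature matrix as MatrixMarket plus a JSON sidecar
#'
#' @param features a `notesieve_features`.
#' @param path base path; writes `<path>.mtx` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "notesieve_features"))
  m <- methods::as(methods::as(features$matrix, "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(path, ".mtx"))
  jsonlite::write_json(list(representation = features$representation,
                            row_ids = rownames(features$matrix),
                            col_names = colnames(features$matrix)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path base path used at write time.
#' @return a `notesieve_features` (vocabulary reduced to column names).
#' @export
read_features <- function(path) {
  m <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(m) <- list(meta$row_ids, meta$col_names)
  vocab <- data.frame(token = meta$col_names %||% character(),
                      index = seq_len(ncol(m)), df = NA_integer_,
                      stringsAsFactors = FALSE)
  new_features(m, vocab, meta$representation)
}
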