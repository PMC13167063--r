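#' Train paragraph-vector document embeddings
#'
#' Trains lightweight document embeddings in the paragraph-vector family:
#' a distributed-memory (DM) sub-model, a distributed bag-of-words (DBOW)
#' sub-model, or both (the default; their vectors are concatenated at
#' inference, the original paragraph-vector recommendation). Output
#' probabilities always use hierarchical softmax over a Huffman tree of
#' corpus word frequencies. Training is single-threaded and fully
#' deterministic under `seed` — the reproducibility mode this package
#' defaults to; it trades away multi-core speed.
#'
#' @param docs character vector of document texts (length >= 10).
#' @param dim dimensionality of each sub-model (default 25, so `"both"`
#'   yields 50-dimensional document vectors).
#' @param window DM context window, in tokens each side.
#' @param epochs training epochs.
#' @param min_count minimum corpus frequency for a token to enter the
#'   vocabulary.
#' @param mode `"both"`, `"dm"`, or `"dbow"`.
#' @param alpha,min_alpha initial and final learning rate (linear decay).
#' @param infer_epochs epochs used when inferring vectors for documents.
#' @param seed integer seed.
#' @param doc_ids optional document ids.
#' @return an object of class `notesieve_embedding` (serializable list of
#'   weight matrices plus the vocabulary and Huffman coding).
#' @export
train_embedding <- function(docs, dim = 25L, window = 5L, epochs = 20L,
                            min_count = 2L, mode = c("both", "dm", "dbow"),
                            alpha = 0.025, min_alpha = 1e-4,
                            infer_epochs = 50L, seed = 1L, doc_ids = NULL) {
  mode <- match.arg(mode)
  if (length(docs) < 10L) {
    stop_user("embedding training requires >= 10 documents, got %d", length(docs))
  }
  ids <- doc_ids %||% names(docs) %||% sprintf("doc%d", seq_along(docs))
  toks <- tokenize(docs)
  if (is.character(toks)) toks <- list(toks)
  counts <- table(unlist(toks))
  counts <- counts[counts >= min_count]
  if (length(counts) < 2L) {
    stop_user("embedding training error: vocabulary has fewer than 2 tokens at min_count=%d",
              min_count)
  }
  # deterministic vocabulary order: frequency desc, token asc
  vocab <- data.frame(token = names(counts), count = as.integer(counts),
                      stringsAsFactors = FALSE)
  vocab <- vocab[order(-vocab$count, vocab$token), ]
  vocab$index <- seq_len(nrow(vocab))
  rownames(vocab) <- NULL
  vmap <- stats::setNames(vocab$index, vocab$token)
  doc_idx <- lapply(toks, function(t) {
    i <- vmap[t]
    as.integer(i[!is.na(i)]) - 1L
  })
  hs <- huffman_coding(vocab$count)
  V <- nrow(vocab)
  sub <- list()
  if (mode %in% c("both", "dm")) {
    sub$dm <- cpp_pv_train(doc_idx, hs$codes, hs$points, V, as.integer(dim),
                           as.integer(window), as.integer(epochs), alpha,
                           min_alpha, TRUE, as.integer(seed))
    rownames(sub$dm$docvecs) <- ids
  }
  if (mode %in% c("both", "dbow")) {
    sub$dbow <- cpp_pv_train(doc_idx, hs$codes, hs$points, V, as.integer(dim),
                             as.integer(window), as.integer(epochs), alpha,
                             min_alpha, FALSE, as.integer(seed) + 1L)
    rownames(sub$dbow$docvecs) <- ids
  }
  structure(list(vocab = vocab, huffman = hs, sub = sub, mode = mode,
                 params = list(dim = as.integer(dim), window = as.integer(window),
                               epochs = as.integer(epochs),
                               min_count = as.integer(min_count),
                               alpha = alpha, min_alpha = min_alpha,
                               infer_epochs = as.integer(infer_epochs),
                               hierarchical_softmax = TRUE,
                               seed = as.integer(seed)),
                 doc_ids = ids),
            class = "notesieve_embedding")
}

#' @export
print.notesieve_embedding <- function(x, ...) {
  cat(sprintf("<notesieve_embedding [%s]: dim %d per sub-model, vocab %d, %d training docs>\n",
              x$mode, x$params$dim, nrow(x$vocab), length(x$doc_ids)))
  invisible(x)
}

#' Embed documents with a trained paragraph-vector model
#'
#' Infers a vector per document against the frozen word and inner-node
#' weights; for mode `"both"` the DM and DBOW vectors are concatenated.
#' Out-of-vocabulary tokens are ignored; a document with no known tokens
#' gets its (deterministic, seed-derived) initialization vector, so the
#' result is always finite.
#'
#' @param model a `notesieve_embedding`.
#' @param docs character vector of texts.
#' @param doc_ids optional row ids.
#' @return a `notesieve_features` with tag `"EMB"` (dense matrix).
#' @export
embed_documents <- function(model, docs, doc_ids = NULL) {
  stopifnot(inherits(model, "notesieve_embedding"))
  ids <- doc_ids %||% names(docs) %||% sprintf("doc%d", seq_along(docs))
  toks <- tokenize(docs)
  if (is.character(toks)) toks <- list(toks)
  vmap <- stats::setNames(model$vocab$index, model$vocab$token)
  doc_idx <- lapply(toks, function(t) {
    i <- vmap[t]
    as.integer(i[!is.na(i)]) - 1L
  })
  p <- model$params
  parts <- list()
  if (!is.null(model$sub$dm)) {
    m <- cpp_pv_infer(doc_idx, model$huffman$codes, model$huffman$points,
                      model$sub$dm$syn0, model$sub$dm$syn1, p$dim, p$window,
                      p$infer_epochs, p$alpha, p$min_alpha, TRUE, p$seed + 1000L)
    colnames(m) <- sprintf("dm_%d", seq_len(ncol(m)))
    parts$dm <- m
  }
  if (!is.null(model$sub$dbow)) {
    m <- cpp_pv_infer(doc_idx, model$huffman$codes, model$huffman$points,
                      model$sub$dbow$syn0, model$sub$dbow$syn1, p$dim, p$window,
                      p$infer_epochs, p$alpha, p$min_alpha, FALSE, p$seed + 2000L)
    colnames(m) <- sprintf("dbow_%d", seq_len(ncol(m)))
    parts$dbow <- m
  }
  m <- do.call(cbind, unname(parts))
  rownames(m) <- ids
  vocab <- data.frame(token = colnames(m), index = seq_len(ncol(m)),
                      df = NA_integer_, stringsAsFactors = FALSE)
  new_features(m, vocab, "EMB")
}

# Huffman coding of the vocabulary by frequency, two-queue construction.
# Returns per-word binary codes (root-to-leaf) and the 0-based inner-node
# index decided at each step.
huffman_coding <- function(counts) {
  V <- length(counts)
  stopifnot(V >= 2)
  ord <- order(counts)            # ascending
  n_nodes <- 2L * V - 1L
  cnt <- c(as.numeric(counts[ord]), rep(Inf, V - 1L))
  parent <- integer(n_nodes)
  binary <- integer(n_nodes)
  pos1 <- V                        # scans leaves downward
  pos2 <- V + 1L                   # scans internal nodes upward
  for (a in seq_len(V - 1L)) {
    take <- function() {
      if (pos1 >= 1L && cnt[pos1] <= cnt[pos2]) {
        i <- pos1; pos1 <<- pos1 - 1L
      } else {
        i <- pos2; pos2 <<- pos2 + 1L
      }
      i
    }
    m1 <- take(); m2 <- take()
    new_node <- V + a
    cnt[new_node] <- cnt[m1] + cnt[m2]
    parent[m1] <- new_node
    parent[m2] <- new_node
    binary[m2] <- 1L
  }
  codes <- vector("list", V)
  points <- vector("list", V)
  for (k in seq_len(V)) {
    j <- k
    bits <- integer()
    nodes <- integer()
    while (parent[j] != 0L) {
      bits <- c(bits, binary[j])
      nodes <- c(nodes, parent[j])
      j <- parent[j]
    }
    w <- ord[k]                    # original word index
    codes[[w]] <- rev(bits)
    points[[w]] <- rev(nodes) - V - 1L   # 0-based inner-node ids
  }
  list(codes = codes, points = points)
}
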