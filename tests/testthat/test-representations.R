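test_that("tokenize lowercases and splits on non-alphanumerics", {
  expect_equal(tokenize("COPD exacerbation, SpO2 88%"),
               c("copd", "exacerbation", "spo2", "88"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("no-known-disease"), c("no", "known", "disease"))
})

test_that("bag-of-words counts and min_df filtering follow the definition", {
  f <- fit_bow(c("a b b", "b c"), min_df = 1)
  expect_equal(colnames(f$matrix), c("a", "b", "c"))
  expect_equal(as.matrix(f$matrix),
               matrix(c(1, 0, 2, 1, 0, 1), 2, 3,
                      dimnames = list(c("doc1", "doc2"), c("a", "b", "c"))))
  f2 <- fit_bow(c("a b b", "b c"), min_df = 2)
  expect_equal(colnames(f2$matrix), "b")
  expect_error(fit_bow(c("", ""), min_df = 1), "empty vocabulary")
})

test_that("TF-IDF matches its stated formula and normalization", {
  # token in every document -> idf = ln(1) + 1 = 1
  f <- fit_tfidf(c("x y", "x z"), min_df = 1)
  expect_equal(f$vocabulary$idf[f$vocabulary$token == "x"],
               log((1 + 2) / (1 + 2)) + 1)
  # single-document corpus: unit row norm
  f1 <- fit_tfidf("a a b", min_df = 1)
  expect_equal(sqrt(sum(as.matrix(f1$matrix)^2)), 1)
})

test_that("BoW and TF-IDF match independent counting oracles", {
  set.seed(11)
  vocab <- c(letters[1:8], "copd", "cough")
  for (rep in 1:10) {
    docs <- vapply(seq_len(sample(2:10, 1)),
                   function(i) random_doc(vocab, sample(3:20, 1)), "")
    mdf <- sample(1:2, 1)
    got_bow <- as.matrix(fit_bow(docs, min_df = mdf)$matrix)
    exp_bow <- oracle_bow(docs, mdf)
    dimnames(got_bow) <- list(NULL, colnames(got_bow))
    expect_equal(got_bow, exp_bow)
    got_tfidf <- as.matrix(fit_tfidf(docs, min_df = mdf)$matrix)
    dimnames(got_tfidf) <- list(NULL, colnames(got_tfidf))
    expect_equal(got_tfidf, oracle_tfidf(docs, mdf), tolerance = 1e-12)
  }
})

test_that("transform_counts projects unseen docs into the fitted space", {
  f <- fit_tfidf(c("a b b c", "b c d", "a d d"), min_df = 1)
  t <- transform_counts(f, c("b zzz b", ""))
  expect_equal(ncol(t$matrix), ncol(f$matrix))   # OOV ignored
  expect_equal(unname(sqrt(sum(as.matrix(t$matrix)[1, ]^2))), 1)  # L2 row
  expect_equal(sum(as.matrix(t$matrix)[2, ]), 0)  # empty doc -> zero row
})

test_that("feature matrices persist via MatrixMarket + JSON sidecar", {
  f <- fit_bow(c("a b b", "b c"), min_df = 1)
  base <- tempfile()
  write_features(f, base)
  back <- read_features(base)
  expect_equal(as.matrix(back$matrix), as.matrix(f$matrix))
  expect_equal(back$representation, "BOW")
  unlink(paste0(base, c(".mtx", ".json")))
})

test_that("embedding output width and determinism follow the contract", {
  tp <- two_topic_docs(10, seed = 2)
  m1 <- train_embedding(tp$docs, dim = 12, epochs = 8, seed = 5)
  X1 <- embed_documents(m1, tp$docs)
  expect_equal(ncol(X1$matrix), 24)  # DM || DBOW concatenation
  expect_false(anyNA(X1$matrix))
  m2 <- train_embedding(tp$docs, dim = 12, epochs = 8, seed = 5)
  X2 <- embed_documents(m2, tp$docs)
  expect_identical(X1$matrix, X2$matrix)
  # single sub-model halves the width
  mdm <- train_embedding(tp$docs, dim = 12, epochs = 4, mode = "dm", seed = 5)
  expect_equal(ncol(embed_documents(mdm, tp$docs[1:2])$matrix), 12)
  expect_error(train_embedding(tp$docs[1:5]), ">= 10 documents")
})

test_that("embeddings separate two disjoint-vocabulary topics", {
  wins <- 0L
  for (s in 1:5) {
    tp <- two_topic_docs(12, seed = s)
    m <- train_embedding(tp$docs, dim = 15, epochs = 15, seed = s)
    M <- embed_documents(m, tp$docs)$matrix
    M <- M / sqrt(rowSums(M^2))
    S <- tcrossprod(M)
    a <- which(tp$labels); b <- which(!tp$labels)
    within <- (mean(S[a, a][upper.tri(S[a, a])]) +
                 mean(S[b, b][upper.tri(S[b, b])])) / 2
    between <- mean(S[a, b])
    if (within > between) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("inference handles unseen and empty documents and recovers training docs", {
  set.seed(4)
  # 20 documents, each over its own small vocabulary, so every document is
  # individually identifiable
  docs <- vapply(1:20, function(i) {
    paste(sample(sprintf("tok%02d_%02d", i, 1:10), 60, TRUE), collapse = " ")
  }, "")
  m <- train_embedding(docs, dim = 15, epochs = 15, seed = 4)
  # only-unseen tokens and empty doc: finite vectors, no error
  odd <- embed_documents(m, c("zzzz qqqq wwww", ""))
  expect_true(all(is.finite(odd$matrix)))
  # a re-inferred training doc sits closer to its training-time vector than
  # to at least 90% of the other docs' training vectors (DM sub-model)
  train_vecs <- m$sub$dm$docvecs
  cossim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (i in c(1, 7, 20)) {
    inf <- embed_documents(m, docs[i])$matrix[1, 1:15]
    sims <- apply(train_vecs, 1, cossim, u = inf)
    expect_gte(mean(sims[i] > sims[-i]), 0.9)
  }
})
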