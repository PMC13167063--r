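# separable toy problem: two Gaussian blobs in 2-D
blob_data <- function(n_per = 10, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per), rnorm(n_per)),
             cbind(rnorm(n_per) + sep, rnorm(n_per) + sep))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c(FALSE, TRUE), each = n_per))
}

test_that("forest fits separable data and is deterministic under seed", {
  d <- blob_data()
  m <- train("rf", d$X, d$y, list(n_trees = 50), seed = 3)
  p <- predict_proba(m, d$X)
  expect_equal(mean((p >= 0.5) == d$y), 1)
  expect_true(all(p >= 0 & p <= 1))
  # deep-in-class point gets a confident probability
  expect_gt(p[20], 0.9)
  m2 <- train("rf", d$X, d$y, list(n_trees = 50), seed = 3)
  expect_identical(p, predict_proba(m2, d$X))
  m3 <- train("rf", d$X, d$y, list(n_trees = 50), seed = 4)
  expect_false(identical(p, predict_proba(m3, d$X)))
})

test_that("boosting fits separable data deterministically", {
  d <- blob_data(seed = 2)
  m <- train("gbt", d$X, d$y, list(n_estimators = 30), seed = 5)
  p <- predict_proba(m, d$X)
  expect_equal(mean((p >= 0.5) == d$y), 1)
  m2 <- train("gbt", d$X, d$y,
              list(n_estimators = 30, subsample = 0.75, colsample_bytree = 0.5),
              seed = 5)
  expect_identical(predict_proba(m2, d$X),
                   predict_proba(train("gbt", d$X, d$y,
                                       list(n_estimators = 30, subsample = 0.75,
                                            colsample_bytree = 0.5),
                                       seed = 5), d$X))
})

test_that("training contracts are enforced", {
  d <- blob_data()
  expect_error(train("rf", d$X, rep(TRUE, nrow(d$X))), "single class")
  m <- train("rf", d$X, d$y, list(n_trees = 20), seed = 1)
  expect_error(predict_proba(m, d$X[, 1, drop = FALSE]), "feature-space")
  expect_error(train("svm", d$X, d$y))
})

test_that("kNN probabilities follow the voting rule", {
  d <- blob_data()
  m1 <- train("knn", d$X, d$y, list(k = 1), seed = 1)
  expect_true(all(predict_proba(m1, d$X) %in% c(0, 1)))
  # k = n -> global positive fraction everywhere (uniform weights)
  mall <- train("knn", d$X, d$y, list(k = nrow(d$X)), seed = 1)
  expect_equal(unique(predict_proba(mall, d$X)), mean(d$y))
  # metrics are accepted
  for (met in c("euclidean", "manhattan", "minkowski")) {
    mm <- train("knn", d$X, d$y, list(k = 3, metric = met), seed = 1)
    expect_true(all(predict_proba(mm, d$X) >= 0))
  }
})

test_that("probabilities behave as binary complements", {
  d <- blob_data(seed = 8)
  for (fam in c("rf", "gbt", "knn")) {
    m <- train(fam, d$X, d$y, seed = 2)
    p <- predict_proba(m, d$X)
    m_flip <- train(fam, d$X, !d$y, seed = 2)
    p_flip <- predict_proba(m_flip, d$X)
    expect_true(all(p >= 0 & p <= 1))
    if (fam == "knn") expect_equal(p + p_flip, rep(1, length(p)))
  }
})

test_that("grid_search selects singleton grids and records 5 fold scores", {
  d <- blob_data(n_per = 15)
  cv <- grid_search("knn", d$X, d$y, grid = list(k = 5L), folds = 5, seed = 1)
  expect_equal(cv$best$k, 5L)
  expect_equal(nrow(cv$scores), 5)
  expect_equal(sort(unique(cv$scores$fold)), 1:5)
  expect_named(cv$summary,
               c("candidate", "f1", "precision", "recall", "specificity"))
})

test_that("grid_search matches an explicit-loop CV oracle per family", {
  d <- blob_data(n_per = 15, sep = 2, seed = 6)   # 30 rows, some overlap
  grids <- list(
    rf = list(n_trees = c(20L, 40L)),
    gbt = list(n_estimators = c(10L, 30L)),
    knn = list(k = c(1L, 7L)))
  for (fam in names(grids)) {
    cv <- grid_search(fam, d$X, d$y, grid = grids[[fam]], folds = 5, seed = 9)
    fold_id <- notesieve:::stratified_folds(d$y, 5, 9)
    cands <- notesieve:::expand_grid_candidates(grids[[fam]])
    expect_equal(cv$best_index,
                 oracle_cv_select(fam, d$X, d$y, cands, fold_id, 9),
                 label = fam)
  }
  # ncd_knn over raw texts
  tp <- two_topic_docs(15, seed = 3)
  cv <- grid_search("ncd_knn", tp$docs, tp$labels, grid = list(k = c(1L, 5L)),
                    folds = 5, seed = 2)
  fold_id <- notesieve:::stratified_folds(tp$labels, 5, 2)
  expect_equal(cv$best_index,
               oracle_cv_select("ncd_knn", tp$docs, tp$labels,
                                notesieve:::expand_grid_candidates(list(k = c(1L, 5L))),
                                fold_id, 2))
})

test_that("under label noise CV prefers the smoother kNN", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    y <- X[, 1] + X[, 2] > 0
    flip <- sample(n, n * 0.2)
    y[flip] <- !y[flip]
    cv <- grid_search("knn", X, y, grid = list(k = c(1L, 15L)), folds = 5,
                      seed = s)
    if (cv$best$k == 15L) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("NCD-kNN follows its voting contract and separates topics", {
  tp <- two_topic_docs(10, seed = 5)
  # query identical to a positive training text, k = 1 -> probability 1
  expect_equal(ncd_knn_classify(tp$docs, tp$labels, tp$docs[1], k = 1), 1)
  # k = |train| -> global positive fraction
  expect_equal(ncd_knn_classify(tp$docs, tp$labels, tp$docs[3], k = 20),
               mean(tp$labels))
  expect_error(ncd_knn_classify(character(0), logical(0), "x", k = 1), "empty")
  expect_error(ncd_knn_classify(tp$docs, tp$labels, "x", k = 99), "exceeds")
  # held-out accuracy on fresh two-topic documents, several seeds
  accs <- vapply(1:5, function(s) {
    tr <- two_topic_docs(20, seed = s)
    te <- two_topic_docs(10, seed = 100 + s)
    p <- ncd_knn_classify(tr$docs, tr$labels, te$docs, k = 5)
    mean((p >= 0.5) == te$labels)
  }, numeric(1))
  expect_true(all(accs > 0.8))
})
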