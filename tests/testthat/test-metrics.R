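test_that("confusion counts orient tp to gold-relevant/predicted-relevant", {
  cm <- confusion(rep("relevant", 5), rep("relevant", 5))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  cm0 <- confusion(character(0), character(0))
  expect_equal(cm0$tp + cm0$fp + cm0$fn + cm0$tn, 0L)
  expect_error(confusion(c("relevant"), character(0)), "lengths differ")
})

test_that("zero denominators yield 0 with the undefined flag", {
  ms <- compute_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(ms$precision, 0)
  expect_true(ms$undefined[["precision"]])
  expect_equal(ms$recall, 0)
  expect_false(ms$undefined[["recall"]])
  expect_equal(ms$specificity, 1)
  expect_true(ms$undefined[["f1"]])
})

test_that("threshold sweep has 11 rows and hand-traceable anchors", {
  tab <- threshold_sweep(c(0.2, 0.9), c("irrelevant", "relevant"))
  expect_s3_class(tab, "notesieve_threshold_table")
  expect_equal(nrow(tab), 11)
  expect_equal(tab$threshold, seq(0, 1, 0.1))
  expect_equal(tab$recall[tab$threshold == 0], 1)   # >= 0 predicts all
  r5 <- tab[tab$threshold == 0.5, ]
  expect_equal(c(r5$tp, r5$tn, r5$f1), c(1, 1, 1))
  expect_error(threshold_sweep(c(1.2), "relevant"), "\\[0, 1\\]")
})

test_that("sweep equals the brute-force oracle and is monotone", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    prob <- round(runif(n), 3)
    gold <- runif(n) < 0.5
    tab <- threshold_sweep(prob, gold)
    orc <- oracle_sweep(prob, gold)
    for (col in colnames(orc)) {
      expect_equal(tab[[col]], unname(orc[, col]), label = col)
    }
    expect_true(all(diff(tab$n_predicted_positive) <= 0))
    expect_true(all(diff(tab$recall) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
  }
})

test_that("select_threshold applies argmax-F1 with its tie-breaks", {
  tab <- threshold_sweep(c(0.35, 0.45, 0.8, 0.9, 0.1),
                         c(rep("relevant", 4), "irrelevant"))
  expect_equal(select_threshold(tab), tab$threshold[which.max(tab$f1)])
  # manual table: tie on F1 -> higher recall wins
  fake <- data.frame(threshold = c(0.2, 0.6), f1 = c(0.8, 0.8),
                     recall = c(0.7, 0.9))
  expect_equal(select_threshold(fake), 0.6)
  # all-equal F1 and recall -> lowest threshold
  flat <- data.frame(threshold = seq(0, 1, 0.1), f1 = 0.5, recall = 0.5)
  expect_equal(select_threshold(flat), 0)
  # recall floor restricts the argmax
  cons <- data.frame(threshold = c(0.2, 0.6), f1 = c(0.7, 0.9),
                     recall = c(0.95, 0.5))
  expect_equal(select_threshold(cons, min_recall = 0.9), 0.2)
})

test_that("bootstrap CIs are deterministic and collapse on perfect predictions", {
  g <- rep(c("relevant", "irrelevant"), 15)
  ci <- bootstrap_ci(g, g, "f1", iterations = 200, seed = 4)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  p <- rep(c("relevant", "irrelevant"), c(20, 10))
  ci1 <- bootstrap_ci(g, p, "f1", iterations = 300, seed = 9)
  ci2 <- bootstrap_ci(g, p, "f1", iterations = 300, seed = 9)
  expect_identical(ci1[c("lower", "upper", "point")],
                   ci2[c("lower", "upper", "point")])
  expect_lte(ci1$lower, ci1$upper)
  # iterations = 1 produces a legal (degenerate-width) interval
  ci_one <- bootstrap_ci(g, p, "f1", iterations = 1, seed = 2)
  expect_equal(ci_one$lower, ci_one$upper)
})

test_that("bootstrap CI width shrinks with sample size", {
  width_at <- function(n, seed) {
    set.seed(seed)
    g <- runif(n) < 0.6
    p <- ifelse(runif(n) < 0.8, g, !g)   # 80%-accurate predictor
    ci <- bootstrap_ci(g, p, "f1", iterations = 300, seed = seed)
    ci$upper - ci$lower
  }
  w50 <- mean(vapply(1:10, function(s) width_at(50, s), numeric(1)))
  w500 <- mean(vapply(1:10, function(s) width_at(500, s), numeric(1)))
  expect_lt(w500, w50)
})

test_that("evaluate_baseline hits the noise-free limit and validates inputs", {
  params <- cohort_params(n_patients = 80, miscoding_rate = 0,
                          uncoded_relevant_rate = 0,
                          pre_window_contamination = 0, seed = 12)
  cohort <- generate_cohort(params)
  pools <- build_pools(cohort$corpus)
  gold <- generate_gold_annotations(cohort, n = 120, seed = 12)
  res <- evaluate_baseline(pools, gold, iterations = 50, seed = 1)
  expect_equal(res$metrics$precision, 1)
  expect_equal(res$metrics$recall, 1)
  expect_equal(res$metrics$specificity, 1)
  expect_equal(res$metrics$f1, 1)
  missing_gold <- data.frame(note_id = "NOPE", label = "relevant")
  expect_error(evaluate_baseline(pools, missing_gold), "missing from pool")
})
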