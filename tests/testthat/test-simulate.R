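test_that("cohort generation is byte-identical under a fixed seed", {
  params <- cohort_params(n_patients = 30, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(params), d1, gold_n = 50, gold_seed = 2)
  write_cohort(generate_cohort(params), d2, gold_n = 50, gold_seed = 2)
  for (f in c("notes.jsonl", "truth.jsonl", "gold.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the corpus
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(cohort_params(n_patients = 30, seed = 43)), d3,
               gold_n = 50, gold_seed = 2)
  expect_false(identical(readLines(file.path(d1, "notes.jsonl")),
                         readLines(file.path(d3, "notes.jsonl"))))
})

test_that("parameter validation rejects infeasible worlds", {
  expect_error(cohort_params(miscoding_rate = 1.2), "parameter error")
  expect_error(cohort_params(encounters_per_patient = c(5, 2)), "parameter error")
  expect_error(cohort_params(study_start = "2020-01-01",
                             study_end = "2020-12-31"),
               "too short")
})

test_that("noise-free generation makes silver pools agree with truth", {
  cohort <- generate_cohort(cohort_params(n_patients = 50, miscoding_rate = 0,
                                          uncoded_relevant_rate = 0,
                                          pre_window_contamination = 0,
                                          seed = 3))
  pools <- build_pools(cohort$corpus)
  merged <- merge(pools, cohort$truth, by = "note_id")
  expect_true(all(merged$relevant[merged$pool == "COPD_ENCOUNTER"]))
  expect_false(any(merged$relevant[merged$pool %in% c("NON_COPD", "PRE_COPD")]))
})

test_that("generator marginals match parameters within binomial tolerance", {
  params <- cohort_params(n_patients = 220, miscoding_rate = 0.3,
                          uncoded_relevant_rate = 0.6, seed = 8)
  cohort <- generate_cohort(params)
  expect_gte(nrow(cohort$truth), 1500)
  merged <- merge(build_pools(cohort$corpus), cohort$truth, by = "note_id")
  # contamination of the positive pool = miscoding rate
  pos <- merged[merged$pool == "COPD_ENCOUNTER", ]
  expect_lt(abs(mean(!pos$relevant) - params$miscoding_rate), 0.05)
  # relevant fraction in uncoded pools = uncoded_relevant_rate
  neg <- merged[merged$pool %in% c("NON_COPD", "PRE_COPD"), ]
  expect_lt(abs(mean(neg$relevant) - params$uncoded_relevant_rate), 0.05)
  # patient-level prevalence
  expect_lt(abs(mean(!is.na(cohort$corpus$patients$first_copd_date)) -
                  params$copd_prevalence), 0.1)
})

test_that("gold annotations honor the 107/100/100 stratified draw", {
  cohort <- generate_cohort(cohort_params(n_patients = 150, seed = 5))
  gold <- generate_gold_annotations(cohort, n = 307, seed = 5)
  expect_equal(nrow(gold), 307)
  branch <- cohort$truth$branch[match(gold$note_id, cohort$truth$note_id)]
  expect_equal(as.integer(table(branch)[c("COPD_ENCOUNTER", "NON_COPD",
                                          "PRE_COPD")]),
               c(107L, 100L, 100L))
  expect_identical(generate_gold_annotations(cohort, n = 307, seed = 5), gold)
  expect_equal(nrow(generate_gold_annotations(cohort, n = 0, seed = 5)), 0)
  expect_error(generate_gold_annotations(cohort, n = 1e6, seed = 5),
               "capacity")
})

test_that("relevant and irrelevant notes are separable by BoW + forest", {
  f1s <- vapply(1:3, function(s) {
    cohort <- generate_cohort(cohort_params(n_patients = 60, seed = s))
    truth <- cohort$truth
    set.seed(s)
    idx <- sample(nrow(truth))
    tr <- idx[1:300]; te <- idx[301:400]
    text <- cohort$corpus$notes$text[match(truth$note_id,
                                           cohort$corpus$notes$note_id)]
    f <- fit_bow(text[tr], min_df = 2)
    m <- train("rf", f, truth$relevant[tr], list(n_trees = 100), seed = s)
    p <- predict_proba(m, transform_counts(f, text[te]))
    ms <- compute_metrics(confusion(truth$relevant[te], p >= 0.5))
    ms$f1
  }, numeric(1))
  expect_true(all(f1s > 0.9))
})
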