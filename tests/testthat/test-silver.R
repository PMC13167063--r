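test_that("assign_pool matches the hand-traced timeline truth table", {
  corpus <- timeline_fixture()
  for (nid in names(timeline_expected_pools)) {
    expect_equal(assign_pool(corpus, nid), unname(timeline_expected_pools[nid]),
                 label = sprintf("pool of %s", nid))
  }
  expect_error(assign_pool(corpus, "NOPE"), "not found")
})

test_that("build_pools partitions every note and matches generator branches", {
  cohort <- generate_cohort(cohort_params(n_patients = 40, seed = 3))
  pools <- build_pools(cohort$corpus)
  expect_equal(nrow(pools), nrow(cohort$truth))
  expect_equal(sum(unlist(attr(pools, "report"))), nrow(cohort$truth))
  # generator records the branch each note was constructed to hit
  got <- pools$pool[match(cohort$truth$note_id, pools$note_id)]
  expect_equal(got, cohort$truth$branch)
})

test_that("degenerate corpora fall into the expected single pools", {
  # no target codes at all -> everything NON_COPD
  notes <- data.frame(note_id = c("N1", "N2"), patient_id = c("P1", "P2"),
                      encounter_id = c("E1", "E2"),
                      date = c("2018-01-01", "2018-02-01"),
                      note_type = "t", text = "x")
  pools <- build_pools(note_corpus(notes))
  expect_true(all(pools$pool == "NON_COPD"))
  # every encounter coded -> no NON_COPD, no PRE_COPD
  codes <- data.frame(encounter_id = c("E1", "E2"), code = "J44.9",
                      system = "ICD10CM")
  pools2 <- build_pools(note_corpus(notes, codes = codes))
  expect_true(all(pools2$pool == "COPD_ENCOUNTER"))
})

test_that("pool labels respect provenance invariants", {
  cohort <- generate_cohort(cohort_params(n_patients = 40, seed = 9))
  corpus <- cohort$corpus
  pools <- build_pools(corpus)
  first_dx <- first_target_dates(corpus)
  names(first_dx) <- corpus$patients$patient_id
  meta <- corpus$notes[match(pools$note_id, corpus$notes$note_id), ]
  # no positive from a patient lacking target codes
  expect_false(any(pools$pool == "COPD_ENCOUNTER" &
                     is.na(first_dx[meta$patient_id])))
  # no NON_COPD note from a patient with any target code
  expect_false(any(pools$pool == "NON_COPD" & !is.na(first_dx[meta$patient_id])))
  # PRE_COPD predates first_copd_date by >= 24 calendar months
  pre <- pools$pool == "PRE_COPD"
  cutoff <- notesieve:::add_months(first_dx[meta$patient_id[pre]], -24L)
  expect_true(all(meta$date[pre] <= cutoff))
})

test_that("training subsets are balanced, deterministic, and validated", {
  cohort <- generate_cohort(cohort_params(n_patients = 80, seed = 2))
  pools <- build_pools(cohort$corpus)
  cfg <- subset_config("MIXED", n_pos = 50, seed = 21)
  sub <- sample_training_subset(pools, cohort$corpus, cfg)
  expect_equal(sum(sub$label == "positive"), 50)
  expect_equal(sum(sub$provenance == "silver:NON_COPD"), 25)
  expect_equal(sum(sub$provenance == "silver:PRE_COPD"), 25)
  expect_false(anyDuplicated(sub$note_id) > 0)
  sub2 <- sample_training_subset(pools, cohort$corpus, cfg)
  expect_identical(sub$note_id, sub2$note_id)
  # different seed moves the draw
  sub3 <- sample_training_subset(pools, cohort$corpus,
                                 subset_config("MIXED", n_pos = 50, seed = 22))
  expect_false(identical(sub$note_id, sub3$note_id))
  # requesting from an empty pool names the deficient pool
  empty_pools <- pools[pools$pool != "PRE_COPD", ]
  class(empty_pools) <- class(pools)
  expect_error(sample_training_subset(empty_pools, cohort$corpus,
                                      subset_config("PRE_ONLY", n_pos = 50)),
               "PRE_COPD")
})

test_that("per-patient cap limits concentration of the draw", {
  cohort <- generate_cohort(cohort_params(n_patients = 80, seed = 2))
  pools <- build_pools(cohort$corpus)
  sub <- sample_training_subset(pools, cohort$corpus,
                                subset_config("MIXED", n_pos = 100, seed = 4))
  pid <- cohort$corpus$notes$patient_id[match(sub$note_id,
                                              cohort$corpus$notes$note_id)]
  # cap applies per pool draw: positives (n=100 -> cap 5)
  pos_counts <- table(pid[sub$label == "positive"])
  expect_true(max(pos_counts) <= ceiling(100 / 20))
})

test_that("gold split is stratified, exhaustive, and validated", {
  cohort <- generate_cohort(cohort_params(n_patients = 150, seed = 6))
  pools <- build_pools(cohort$corpus)
  gold <- generate_gold_annotations(cohort, n = 307, seed = 6)
  split <- split_gold(gold, pools, validation_n = 84, seed = 6)
  expect_equal(nrow(split$validation), 84)
  expect_equal(nrow(split$test), 223)
  expect_length(intersect(split$validation$note_id, split$test$note_id), 0)
  # both splits see all three pools of origin
  origin <- function(ids) unique(pools$pool[match(ids, pools$note_id)])
  expect_setequal(origin(split$validation$note_id),
                  c("COPD_ENCOUNTER", "NON_COPD", "PRE_COPD"))
  # boundary: validation_n = 0
  split0 <- split_gold(gold, pools, validation_n = 0, seed = 6)
  expect_equal(nrow(split0$validation), 0)
  expect_equal(nrow(split0$test), 307)
  # duplicate and unknown ids are referential errors
  dup <- rbind(gold, gold[1, ])
  expect_error(split_gold(dup, pools, 10), "duplicate")
  bad <- gold; bad$note_id[1] <- "ZZZ"
  expect_error(split_gold(bad, pools, 10), "unknown")
})

test_that("pool files round-trip as line-delimited JSON", {
  corpus <- timeline_fixture()
  pools <- build_pools(corpus)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_pools(pools, path)
  back <- read_pools(path)
  expect_equal(back$note_id, pools$note_id)
  expect_equal(back$pool, pools$pool)
  expect_equal(back$label, pools$label)
})
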