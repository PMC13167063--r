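test_that("extract_concepts finds affirmed and negated mentions", {
  lex <- toy_lexicon()
  # the canonical anchor: heart -> C0018787
  got <- extract_concepts("the heart appears normal", lex)
  expect_equal(got$concept_id, "C0018787")
  expect_equal(got$assertion, 1L)
  # trigger within 6 preceding tokens, same sentence -> negated
  neg <- extract_concepts("no evidence of emphysema", lex)
  expect_equal(neg$assertion, -1L)
  expect_equal(neg$concept_id,
               lex$terms$concept_id[lex$terms$term == "emphysema"])
  expect_equal(nrow(extract_concepts("", lex)), 0)
})

test_that("negation window is 6 tokens and sentence-bounded", {
  lex <- toy_lexicon()
  # 7 tokens between trigger and mention: out of window
  far <- extract_concepts("no one two three four five six seven cough", lex)
  expect_equal(far$assertion[far$term == "cough"], 1L)
  # sentence boundary blocks the trigger
  bounded <- extract_concepts("denies fever. cough is present", lex)
  expect_equal(bounded$assertion[bounded$term == "cough"], 1L)
  within <- extract_concepts("patient denies any cough", lex)
  expect_equal(within$assertion[within$term == "cough"], -1L)
})

test_that("greedy longest match wins over sub-terms", {
  lex <- toy_lexicon()
  got <- extract_concepts("chronic obstructive pulmonary disease confirmed", lex)
  expect_equal(got$concept_id[1], "C5000001")
  expect_equal(got$term[1], "chronic obstructive pulmonary disease")
})

test_that("concept vectors encode assertion with affirmation dominance", {
  lex <- toy_lexicon()
  f <- concept_vectorize("severe emphysema and dyspnea", lex)
  m <- f$matrix
  expect_true(all(m %in% c(-1, 0, 1)))
  expect_equal(sum(m != 0), 2)
  # affirmed and negated in one doc -> +1 by default, -1 when flipped
  doc <- "no emphysema seen. later severe emphysema found"
  cid <- lex$terms$concept_id[lex$terms$term == "emphysema"]
  expect_equal(unname(concept_vectorize(doc, lex)$matrix[1, cid]), 1)
  expect_equal(unname(concept_vectorize(doc, lex,
                                        negation_dominates = TRUE)$matrix[1, cid]),
               -1)
})

test_that("concept_vectorize equals a brute-force per-document oracle", {
  lex <- toy_lexicon()
  set.seed(13)
  terms <- lex$terms$term
  docs <- vapply(1:10, function(i) {
    n <- sample(3:8, 1)
    paste(ifelse(runif(n) < 0.3, "no", ""), sample(terms, n, TRUE),
          collapse = ". ")
  }, "")
  got <- concept_vectorize(docs, lex)$matrix
  for (d in seq_along(docs)) {
    ex <- extract_concepts(docs[d], lex)
    expected <- setNames(rep(0, length(lex$concept_ids)), lex$concept_ids)
    for (cid in unique(ex$concept_id)) {
      a <- ex$assertion[ex$concept_id == cid]
      expected[cid] <- if (any(a > 0)) 1 else -1
    }
    expect_equal(got[d, ], expected, label = sprintf("doc %d", d))
  }
})

test_that("lexicon files load with case-insensitive lookup", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tconcept_id", "Heart\tC0018787"), path)
  lex <- read_lexicon(path)
  expect_equal(extract_concepts("HEART", lex)$concept_id, "C0018787")
})
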