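test_that("read_corpus links a small JSONL fixture", {
  lines <- c(
    '{"note_id":"N1","patient_id":"P1","encounter_id":"E1","date":"2018-01-01","note_type":"progress","text":"a","codes":[{"code":"J44.9","system":"ICD10CM"}]}',
    '{"note_id":"N2","patient_id":"P1","encounter_id":"E1","date":"2018-01-01","note_type":"progress","text":"b","codes":[{"code":"J44.9","system":"ICD10CM"}]}',
    '{"note_id":"N3","patient_id":"P1","encounter_id":"E2","date":"2019-02-02","note_type":"discharge","text":"c","codes":[]}')
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(lines, path)
  corpus <- read_corpus(path)
  expect_equal(nrow(corpus$notes), 3)
  expect_equal(nrow(corpus$encounters), 2)
  expect_equal(nrow(corpus$patients), 1)
  expect_equal(corpus$patients$first_copd_date, as.Date("2018-01-01"))
})

test_that("malformed and inconsistent input raise named errors", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"note_id":"N1"', ""), path)
  expect_error(read_corpus(path), "line 1")
  writeLines('{"note_id":"N1","patient_id":"P1","date":"2018-01-01","note_type":"t","text":"x"}',
             path)
  expect_error(read_corpus(path), "encounter_id")
  # programmatic construction with a dangling encounter reference
  notes <- data.frame(note_id = "N1", patient_id = "P1", encounter_id = "E9",
                      date = "2018-01-01", note_type = "t", text = "x")
  enc <- data.frame(encounter_id = "E1", patient_id = "P1", date = "2018-01-01")
  expect_error(note_corpus(notes, encounters = enc), "referential integrity")
})

test_that("empty file gives an empty corpus without error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  file.create(path)
  corpus <- read_corpus(path)
  expect_equal(nrow(corpus$notes), 0)
  expect_equal(nrow(corpus$patients), 0)
})

test_that("write/read round-trips reproduce the corpus on random corpora", {
  for (s in 1:50) {
    corpus <- random_mini_corpus(n_patients = sample(1:4, 1), seed = s)
    path <- withr::local_tempfile(fileext = ".jsonl")
    write_corpus(corpus, path)
    back <- read_corpus(path)
    expect_equal(back$notes, corpus$notes)
    expect_equal(back$encounters, corpus$encounters)
    expect_equal(back$codes, corpus$codes)
    expect_equal(back$patients, corpus$patients)
  }
})

test_that("unicode clinical text survives the round-trip exactly", {
  notes <- data.frame(note_id = "N1", patient_id = "P1", encounter_id = "E1",
                      date = "2018-01-01", note_type = "t",
                      text = "temp ≥ 38°, naïve")
  corpus <- note_corpus(notes)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  expect_identical(read_corpus(path)$notes$text, corpus$notes$text)
})

test_that("empty corpus writes a valid empty file", {
  corpus <- note_corpus(data.frame())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  expect_equal(nrow(read_corpus(path)$notes), 0)
})

test_that("first_target_dates is the minimum coded-encounter date, NA if none", {
  for (s in 1:20) {
    corpus <- random_mini_corpus(n_patients = 3, seed = 100 + s)
    got <- first_target_dates(corpus)
    cs <- copd_codeset()
    for (i in seq_len(nrow(corpus$patients))) {
      pid <- corpus$patients$patient_id[i]
      enc <- corpus$encounters[corpus$encounters$patient_id == pid, ]
      coded_dates <- as.Date(character())
      for (j in seq_len(nrow(enc))) {
        cd <- corpus$codes[corpus$codes$encounter_id == enc$encounter_id[j], ]
        if (nrow(cd) && any(is_target_code(cd[, c("system", "normalized")], cs))) {
          coded_dates <- c(coded_dates, enc$date[j])
        }
      }
      if (length(coded_dates)) {
        expect_equal(got[i], min(coded_dates))
      } else {
        expect_true(is.na(got[i]))
      }
    }
  }
})
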