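lex <- demo_lexicon()

test_that("the feature matrix has one row per note with planted states", {
  notes <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    note_id = c("N1", "N2", "N3"),
    note_date = as.Date(c("2000-01-01", "2000-02-01", "2001-01-01")),
    text = c("rheumatoid arthritis active", "denies myocardial infarction",
             "started Vioxx")
  )
  mat <- build_feature_matrix(annotate_notes(notes, lex), notes = notes)
  expect_equal(nrow(mat$rows), 3)
  expect_equal(mat$cells$state[mat$cells$note_id == "N1" &
                               mat$cells$concept_id == "C_RA"], "positive")
  expect_equal(mat$cells$state[mat$cells$note_id == "N2" &
                               mat$cells$concept_id == "C_MI"], "negated")
  tidy_m <- tidy(mat)
  expect_true(all(c("patient_id", "note_date", "state") %in% names(tidy_m)))
})

test_that("duplicate note rows are rejected with a warning", {
  notes <- tibble::tibble(
    patient_id = c("P1", "P1"),
    note_id = c("N1", "N1"),
    note_date = as.Date(c("2000-01-01", "2000-06-01")),
    text = "rheumatoid arthritis"
  )
  expect_warning(mat <- build_feature_matrix(annotate_notes(notes, lex),
                                             notes = notes),
                 "duplicate")
  expect_equal(nrow(mat$rows), 1)
  expect_equal(mat$rows$note_date, as.Date("2000-01-01"))
})

test_that("feature matrix serialization round-trips losslessly", {
  corpus <- generate_corpus(synth_config(cells = c(a = 2, b = 1, c = 1, d = 2),
                                         seed = 5))
  mat <- build_feature_matrix(annotate_notes(corpus$notes, lex),
                              notes = corpus$notes)
  dir <- withr::local_tempdir()
  write_feature_matrix(mat, dir)
  back <- read_feature_matrix(dir)
  expect_equal(back$rows, mat$rows)
  expect_equal(back$cells, mat$cells)
})

test_that("synthetic ground truth is recovered in the feature matrix", {
  cfg <- synth_config(cells = c(a = 4, b = 2, c = 2, d = 2),
                      notes_per_patient = c(1, 1), seed = 21)
  corpus <- generate_corpus(cfg)
  mat <- build_feature_matrix(annotate_notes(corpus$notes,
                                             normalize_lexicon(synth_lexicon(),
                                                               synth_concept_map())),
                              notes = corpus$notes)
  expect_equal(nrow(mat$rows), nrow(corpus$notes))
  truth <- dplyr::arrange(corpus$truth$mentions, note_id, concept_id)
  got <- dplyr::arrange(mat$cells, note_id, concept_id)
  expect_equal(got$note_id, truth$note_id)
  expect_equal(got$concept_id, truth$concept_id)
  expect_equal(got$state == "negated", truth$negated)
})

test_that("ICD-9 codes map by longest prefix and unmapped codes drop", {
  recs <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    date = as.Date("2000-01-01") + 0:3,
    icd9_code = c("714.0", "410.1", "250.0", "4109")
  )
  map <- tibble::tibble(prefix = c("714", "410", "4109"),
                        concept_id = c("C_RA", "C_MI", "C_OTHER"))
  out <- suppressMessages(ingest_icd9(recs, map))
  expect_equal(out$concept_id[out$patient_id == "P1"], "C_RA")
  expect_equal(out$concept_id[out$patient_id == "P2"], "C_MI")
  expect_false("P3" %in% out$patient_id)
  expect_equal(out$concept_id[out$patient_id == "P4"], "C_OTHER")
  expect_true(all(out$provenance == "coded"))
  # named-vector map form
  out2 <- suppressMessages(ingest_icd9(recs, c("714" = "C_RA")))
  expect_equal(out2$patient_id, "P1")
})

test_that("timelines order events by date with notes before coded on ties", {
  notes <- tibble::tibble(
    patient_id = "P1",
    note_id = c("N2", "N1"),
    note_date = as.Date(c("2000-01-01", "1999-06-01")),
    text = c("Vioxx started", "rheumatoid arthritis")
  )
  mat <- build_feature_matrix(annotate_notes(notes, lex), notes = notes)
  coded <- suppressMessages(ingest_icd9(
    tibble::tibble(patient_id = "P1", date = as.Date("2000-01-01"),
                   icd9_code = "714.1"),
    c("714" = "C_RA")))
  tl <- build_timelines(mat, coded)
  expect_equal(tl$timestamp, sort(tl$timestamp))
  same_day <- tl[tl$timestamp == as.Date("2000-01-01"), ]
  expect_equal(same_day$provenance, c("note", "coded"))
  # coded-only patient
  coded2 <- suppressMessages(ingest_icd9(
    tibble::tibble(patient_id = "P9", date = as.Date("2001-01-01"),
                   icd9_code = "410.0"),
    c("410" = "C_MI")))
  tl2 <- build_timelines(mat, coded2)
  expect_equal(tl2$provenance[tl2$patient_id == "P9"], "coded")
})

test_that("timeline timestamps are non-decreasing within every patient", {
  corpus <- generate_corpus(synth_config(cells = c(a = 5, b = 3, c = 3, d = 4),
                                         icd9_fraction = 0.5, seed = 9))
  mat <- build_feature_matrix(annotate_notes(corpus$notes,
                                             normalize_lexicon(synth_lexicon(),
                                                               synth_concept_map())),
                              notes = corpus$notes)
  coded <- suppressMessages(ingest_icd9(corpus$coded, synth_code_map()))
  tl <- build_timelines(mat, coded)
  by_pat <- split(tl$timestamp, tl$patient_id)
  expect_true(all(vapply(by_pat, function(x) !is.unsorted(x), logical(1))))
})

test_that("cohort selection requires a positive mention and is monotone", {
  notes <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    note_id = c("N1", "N2", "N3"),
    note_date = as.Date("2000-01-01") + 0:2,
    text = c("rheumatoid arthritis confirmed",
             "no evidence of rheumatoid arthritis",
             "started Vioxx")
  )
  mat <- build_feature_matrix(annotate_notes(notes, lex), notes = notes)
  tl <- build_timelines(mat)
  ra_only <- select_cohort(tl, "C_RA")
  expect_setequal(unique(ra_only$patient_id), "P1")  # negated-only P2 excluded
  both <- select_cohort(tl, c("C_RA", "C_VIOXX"))
  expect_setequal(unique(both$patient_id), c("P1", "P3"))
  # enlarging the concept set never shrinks the cohort
  expect_true(all(unique(ra_only$patient_id) %in% unique(both$patient_id)))
  # retained timelines are unmodified
  expect_equal(ra_only, tl[tl$patient_id == "P1", ])
})

test_that("window filtering keeps only events inside inclusive bounds", {
  tl <- make_timeline("P1", c(-367, 0, 200, 2193),
                      c("C_RA", "C_RA", "C_MI", "C_MI"))
  # dates: 1998-12-31, 2000-01-01, 2000-07-19, 2006-01-03
  out <- filter_window(tl, "1999-01-01", "2004-12-31")
  expect_equal(out$timestamp,
               as.Date(c("2000-01-01", "2000-07-19")))
  expect_error(filter_window(tl, "2005-01-01", "1999-01-01"))
})
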