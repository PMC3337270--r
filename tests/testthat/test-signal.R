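tq <- triplet_query("C_RA", "C_ROFECOXIB", "C_MI")

test_that("triplet queries validate their window and concepts", {
  expect_error(triplet_query("C_RA", "C_RA", "C_MI"), "distinct")
  expect_error(triplet_query("C_RA", "C_X", "C_MI",
                             "2005-01-01", "1999-01-01"), "window")
})

test_that("canonical temporal patterns land in their cells", {
  # condition -> drug -> event: the risk pattern, cell A
  a_tl <- make_timeline("PA", c(0, 366, 731), c("C_RA", "C_ROFECOXIB", "C_MI"))
  expect_equal(classify_patients(a_tl, tq)$cell, "A")
  # condition -> drug, no event: cell B
  b_tl <- make_timeline("PB", c(0, 366), c("C_RA", "C_ROFECOXIB"))
  expect_equal(classify_patients(b_tl, tq)$cell, "B")
  # condition -> event, no drug: cell C
  c_tl <- make_timeline("PC", c(0, 366), c("C_RA", "C_MI"))
  expect_equal(classify_patients(c_tl, tq)$cell, "C")
  # condition only: cell D
  d_tl <- make_timeline("PD", 0, "C_RA")
  expect_equal(classify_patients(d_tl, tq)$cell, "D")
  # drug before condition / event before condition / no condition: excluded
  x1 <- make_timeline("PX", c(0, 366), c("C_ROFECOXIB", "C_RA"))
  x2 <- make_timeline("PY", c(0, 366), c("C_MI", "C_RA"))
  x3 <- make_timeline("PZ", c(0, 366), c("C_ROFECOXIB", "C_MI"))
  expect_equal(classify_patients(x1, tq)$reason, "prior_drug")
  expect_equal(classify_patients(x2, tq)$reason, "prevalent_event")
  expect_equal(classify_patients(x3, tq)$reason, "no_condition")
})

test_that("same-day mentions do not establish succession unless ties are weak", {
  tl <- make_timeline("P1", c(0, 0, 366), c("C_RA", "C_ROFECOXIB", "C_MI"))
  expect_equal(classify_patients(tl, tq, ties = "strict")$cell, "C")
  expect_equal(classify_patients(tl, tq, ties = "weak")$cell, "A")
})

test_that("policy flags re-route prior-drug and prevalent-event patients", {
  prior <- make_timeline("P1", c(0, 366, 731),
                         c("C_ROFECOXIB", "C_RA", "C_MI"))
  expect_equal(classify_patients(prior, tq)$cell, "EXCLUDED")
  expect_equal(classify_patients(prior, tq,
                                 prior_drug_policy = "unexposed")$cell, "C")
  prev <- make_timeline("P2", c(0, 366, 731, 1096),
                        c("C_MI", "C_RA", "C_ROFECOXIB", "C_MI"))
  expect_equal(classify_patients(prev, tq)$cell, "EXCLUDED")
  expect_equal(classify_patients(prev, tq,
                                 prevalent_event_policy = "keep")$cell, "A")
})

test_that("classification matches the brute-force rules on all order types", {
  # every assignment of first-mention days from {absent, 1, 2, 3} incl. ties
  vals <- list(NULL, 1, 2, 3)
  grid <- expand.grid(ci = 1:4, di = 1:4, ei = 1:4)
  policies <- expand.grid(ties = c("strict", "weak"),
                          pd = c("exclude", "unexposed"),
                          pe = c("exclude", "keep"),
                          stringsAsFactors = FALSE)
  for (p in seq_len(nrow(policies))) {
    for (g in seq_len(nrow(grid))) {
      cd <- vals[[grid$ci[g]]]
      dd <- vals[[grid$di[g]]]
      ed <- vals[[grid$ei[g]]]
      dates <- c(cd, dd, ed)
      if (is.null(dates)) next
      concepts <- c(rep("C_RA", length(cd)), rep("C_ROFECOXIB", length(dd)),
                    rep("C_MI", length(ed)))
      tl <- make_timeline("P1", dates, concepts)
      got <- classify_patients(tl, tq, ties = policies$ties[p],
                               prior_drug_policy = policies$pd[p],
                               prevalent_event_policy = policies$pe[p])$cell
      want <- oracle_classify(cd, dd, ed, ties = policies$ties[p],
                              prior_drug_policy = policies$pd[p],
                              prevalent_event_policy = policies$pe[p])
      expect_equal(got, want,
                   info = sprintf("cond=%s drug=%s evt=%s policy=%d",
                                  deparse(cd), deparse(dd), deparse(ed), p))
    }
  }
})

test_that("classification matches the brute-force rules on random multi-mention timelines", {
  withr::with_seed(77, {
    for (rep in 1:300) {
      cd <- sort(sample(0:6, sample(0:3, 1)))
      dd <- sort(sample(0:6, sample(0:3, 1)))
      ed <- sort(sample(0:6, sample(0:3, 1)))
      if (!length(c(cd, dd, ed))) next
      tl <- make_timeline("P1", c(cd, dd, ed),
                          c(rep("C_RA", length(cd)),
                            rep("C_ROFECOXIB", length(dd)),
                            rep("C_MI", length(ed))))
      pol <- list(ties = sample(c("strict", "weak"), 1),
                  pd = sample(c("exclude", "unexposed"), 1),
                  pe = sample(c("exclude", "keep"), 1))
      got <- classify_patients(tl, tq, ties = pol$ties,
                               prior_drug_policy = pol$pd,
                               prevalent_event_policy = pol$pe)$cell
      want <- oracle_classify(cd, dd, ed, ties = pol$ties,
                              prior_drug_policy = pol$pd,
                              prevalent_event_policy = pol$pe)
      expect_equal(got, want)
    }
  })
})

test_that("negated mentions never satisfy positive predicates downstream", {
  # an A-pattern patient whose event mention is negated falls into cell B
  tl <- make_timeline("P1", c(0, 366, 731), c("C_RA", "C_ROFECOXIB", "C_MI"),
                      states = c("positive", "positive", "negated"))
  expect_equal(classify_patients(tl, tq)$cell, "B")
  # a patient whose only condition mention is negated is not in the cohort
  tl2 <- make_timeline("P2", c(0, 366), c("C_RA", "C_ROFECOXIB"),
                       states = c("negated", "positive"))
  expect_equal(classify_patients(tl2, tq)$reason, "no_condition")
})

test_that("contingency counts conserve patients and reflect planted cells", {
  cfg <- synth_config(cells = c(a = 3, b = 2, c = 2, d = 5),
                      excluded = c(no_condition = 2, prior_drug = 1,
                                   prevalent_event = 1),
                      negation_rate = 0.3, seed = 13)
  corpus <- generate_corpus(cfg)
  lex <- normalize_lexicon(synth_lexicon(), synth_concept_map())
  mat <- build_feature_matrix(annotate_notes(corpus$notes, lex),
                              notes = corpus$notes)
  tl <- filter_window(build_timelines(mat), tq$window_start, tq$window_end)
  tab <- build_contingency(tl, tq)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3, 2, 2, 5))
  expect_equal(unname(tab$excluded),
               c(no_condition = 2L, prior_drug = 1L, prevalent_event = 1L),
               ignore_attr = TRUE)
  # conservation: cells + excluded = patients entering classification
  expect_equal(tab$a + tab$b + tab$c + tab$d + sum(tab$excluded),
               dplyr::n_distinct(tl$patient_id))
})

test_that("narrowing the window never increases cell a", {
  withr::with_seed(41, {
    corpus <- generate_corpus(synth_config(cells = c(a = 6, b = 4, c = 4, d = 6),
                                           seed = 17))
    lex <- normalize_lexicon(synth_lexicon(), synth_concept_map())
    mat <- build_feature_matrix(annotate_notes(corpus$notes, lex),
                                notes = corpus$notes)
    tl <- build_timelines(mat)
    windows <- list(c("1999-01-01", "2004-12-31"),
                    c("1999-07-01", "2004-06-30"),
                    c("2000-01-01", "2003-12-31"),
                    c("2001-01-01", "2002-12-31"))
    a_prev <- Inf
    for (w in windows) {
      tab <- build_contingency(filter_window(tl, w[1], w[2]), tq)
      expect_lte(tab$a, a_prev)
      a_prev <- tab$a
    }
  })
})

test_that("test_signal runs the full pipeline and is deterministic", {
  cfg <- synth_config(cells = c(a = 3, b = 2, c = 2, d = 5), seed = 3)
  corpus <- generate_corpus(cfg)
  lex <- normalize_lexicon(synth_lexicon(), synth_concept_map())
  mat <- build_feature_matrix(annotate_notes(corpus$notes, lex),
                              notes = corpus$notes)
  res1 <- test_signal(mat, tq)
  res2 <- test_signal(mat, tq)
  expect_identical(res1, res2)
  expect_equal(tidy(res1)$a, 3)
  expect_equal(tidy(res1)$estimate, (3 * 5) / (2 * 2))
  g <- glance(res1)
  expect_equal(g$n, 12)
})

test_that("deleting all drug mentions empties the exposed arm with a flag", {
  cfg <- synth_config(cells = c(a = 3, b = 2, c = 2, d = 5), seed = 3)
  corpus <- generate_corpus(cfg)
  lex <- normalize_lexicon(synth_lexicon(), synth_concept_map())
  ann <- annotate_notes(corpus$notes, lex)
  ann <- ann[ann$concept_id != "C_ROFECOXIB", ]
  mat <- build_feature_matrix(ann, notes = corpus$notes)
  res <- test_signal(mat, tq)
  expect_equal(res$table$a, 0)
  expect_equal(res$table$b, 0)
  expect_true("undefined-odds-ratio" %in% res$flags)
  expect_true(is.na(res$estimate))
})

test_that("ICD-9-only mode ignores text-derived condition and event mentions", {
  # notes mention MI, but there is no 410* coded record: the event must
  # never be detected in coded-only mode
  notes <- tibble::tibble(
    patient_id = "P1",
    note_id = c("N1", "N2", "N3"),
    note_date = as.Date(c("2000-01-01", "2001-01-01", "2002-01-01")),
    text = c("rheumatoid arthritis", "Vioxx started",
             "myocardial infarction today")
  )
  lex <- normalize_lexicon(demo_lexicon(), synth_concept_map())
  mat <- build_feature_matrix(annotate_notes(notes, lex), notes = notes)
  coded <- suppressMessages(ingest_icd9(
    tibble::tibble(patient_id = "P1", date = as.Date("2000-01-01"),
                   icd9_code = "714.0"),
    synth_code_map()))
  res <- test_signal(mat, tq, coded = coded, icd9_only = TRUE)
  # exposed (coded RA then text drug), but no coded event: cell B
  expect_equal(c(res$table$a, res$table$b, res$table$c, res$table$d),
               c(0, 1, 0, 0))
  # with the matching coded event the same patient lands in cell A
  coded2 <- suppressMessages(ingest_icd9(
    tibble::tibble(patient_id = "P1",
                   date = as.Date(c("2000-01-01", "2002-01-01")),
                   icd9_code = c("714.0", "410.1")),
    synth_code_map()))
  res2 <- test_signal(mat, tq, coded = coded2, icd9_only = TRUE)
  expect_equal(res2$table$a, 1)
})
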