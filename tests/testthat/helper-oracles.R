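# Independent brute-force oracles used to certify the implementation, plus
# small fixture builders. These re-derive expected results by a different
# route than the package code.

# --- term-matching oracle -----------------------------------------------
# Regex alternation over a token-normalized copy of the text: every
# token-aligned occurrence of every surface is enumerated, then maximal
# matches are kept with the longest-span / leftmost rule.
oracle_match <- function(text, lexicon) {
  tk <- adesignal::tokenize(text)
  if (nrow(tk) == 0 || nrow(lexicon) == 0) {
    return(tibble::tibble(concept_id = character(), start = integer(),
                          end = integer()))
  }
  toks <- tolower(tk$token)
  joined <- paste(toks, collapse = " ")
  # start position (1-based, in `joined`) of each token
  jstart <- cumsum(c(1L, nchar(toks) + 1L))[seq_along(toks)]
  hits <- list()
  surfaces <- unique(lexicon[, c("surface", "concept_id")])
  for (r in seq_len(nrow(surfaces))) {
    key_toks <- strsplit(tolower(surfaces$surface[r]), "[^[:alnum:]]+")[[1]]
    key_toks <- key_toks[nzchar(key_toks)]
    if (!length(key_toks)) next
    key <- paste(key_toks, collapse = " ")
    pat <- paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", key),
                  "(?![[:alnum:]])")
    m <- gregexpr(pat, joined, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (pos in as.integer(m)) {
      ti <- match(pos, jstart)
      if (is.na(ti)) next  # not token-aligned
      tj <- ti + length(key_toks) - 1L
      hits[[length(hits) + 1L]] <- data.frame(
        concept_id = surfaces$concept_id[r],
        start = tk$start[ti], end = tk$end[tj],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(concept_id = character(), start = integer(),
                          end = integer()))
  }
  all_m <- unique(do.call(rbind, hits))
  # keep all concepts per span; resolve span overlaps longest-first, leftmost
  spans <- unique(all_m[, c("start", "end")])
  spans <- spans[order(-(spans$end - spans$start), spans$start), ]
  kept <- spans[0, ]
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    if (!any(s$start < kept$end & s$end > kept$start)) kept <- rbind(kept, s)
  }
  out <- merge(all_m, kept, by = c("start", "end"))
  out <- out[order(out$start, out$concept_id), ]
  tibble::tibble(concept_id = out$concept_id, start = as.integer(out$start),
                 end = as.integer(out$end))
}

# --- patient-classification oracle --------------------------------------
# Direct transcription of the cell rules onto explicit occurrence date
# vectors, bypassing the timeline machinery entirely.
oracle_classify <- function(cond_dates, drug_dates, evt_dates,
                            ties = "strict",
                            prior_drug_policy = "exclude",
                            prevalent_event_policy = "exclude") {
  lt <- if (ties == "strict") `<` else `<=`
  if (!length(cond_dates)) return("EXCLUDED")
  tc <- min(cond_dates)
  td <- if (length(drug_dates)) min(drug_dates) else NA
  te <- if (length(evt_dates)) min(evt_dates) else NA
  if (!is.na(td) && td < tc && prior_drug_policy == "exclude") return("EXCLUDED")
  if (!is.na(te) && te < tc) {
    if (prevalent_event_policy == "exclude") return("EXCLUDED")
    later <- evt_dates[lt(tc, evt_dates)]
    te <- if (length(later)) min(later) else NA
  }
  exposed <- !is.na(td) && lt(tc, td)
  if (exposed) {
    if (!is.na(te) && lt(td, te)) "A" else "B"
  } else {
    if (!is.na(te) && lt(tc, te)) "C" else "D"
  }
}

# --- Fisher enumeration oracle ------------------------------------------
# Exhaustive enumeration of all margin-consistent tables via binomial
# coefficients (no dhyper), point-probability two-sided definition.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# --- fixture builders ----------------------------------------------------
# A per-patient timeline tibble from compact event triples.
make_timeline <- function(patient_id, dates, concepts,
                          states = "positive", provenance = "note") {
  n <- length(dates)
  tibble::tibble(
    patient_id = patient_id,
    timestamp = as.Date("2000-01-01") + as.integer(dates),
    concept_id = concepts,
    state = rep_len(states, n),
    provenance = rep_len(provenance, n),
    note_id = sprintf("%s-N%02d", patient_id, seq_len(n))
  )
}

write_lexicon_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

demo_lexicon <- function() {
  tibble::tibble(
    surface = c("arthritis", "rheumatoid arthritis", "Vioxx", "rofecoxib",
                "myocardial infarction"),
    concept_id = c("C_ART", "C_RA", "C_VIOXX", "C_ROFECOXIB", "C_MI"),
    source = "TEST"
  )
}

# random token vocabulary for matcher property tests
rand_word <- function(n) {
  syll <- c("ka", "lo", "mi", "ru", "ta", "ne", "vo", "se", "dal", "bri")
  vapply(seq_len(n), function(i) {
    paste(sample(syll, sample(1:3, 1), replace = TRUE), collapse = "")
  }, character(1))
}
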