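# Synthetic note corpora with planted temporal patterns. The generator emits
# the same JSON-lines note format and ICD-9 CSV the pipeline consumes, plus
# the planted ground truth, so the full annotate -> timeline -> signal chain
# can be validated without any clinical data.

#' Demonstration lexicon used by the synthetic corpus generator
#'
#' Triplet concepts (rheumatoid arthritis, Vioxx/rofecoxib, myocardial
#' infarction) plus a few bystander conditions used as noise.
#'
#' @return A lexicon tibble (`surface`, `concept_id`, `source`).
#' @export
synth_lexicon <- function() {
  tibble(
    surface = c("rheumatoid arthritis", "Vioxx", "rofecoxib",
                "myocardial infarction", "diabetes mellitus", "hypertension",
                "peptic ulcer", "asthma"),
    concept_id = c("C_RA", "C_VIOXX", "C_ROFECOXIB",
                   "C_MI", "C_DM", "C_HTN", "C_ULCER", "C_ASTHMA"),
    source = "SYNTH"
  )
}

#' Concept-normalization mapping for the synthetic lexicon
#'
#' Maps the trade-name concept for Vioxx onto its active ingredient,
#' rofecoxib, mirroring RxNorm-style trade-name normalization.
#'
#' @return A mapping tibble (`concept_id`, `canonical_id`).
#' @export
synth_concept_map <- function() {
  tibble(concept_id = "C_VIOXX", canonical_id = "C_ROFECOXIB")
}

#' ICD-9 prefix map for the synthetic corpus
#'
#' Rheumatoid arthritis codes begin with 714; myocardial infarction codes
#' begin with 410.
#'
#' @return A tibble (`prefix`, `concept_id`).
#' @export
synth_code_map <- function() {
  tibble(prefix = c("714", "410"), concept_id = c("C_RA", "C_MI"))
}

#' Configure a synthetic corpus
#'
#' @param cells Named integer vector `c(a, b, c, d)`: number of patients
#'   planted for each contingency cell (a: condition, then drug, then event;
#'   b: condition then drug, no event; c: condition then event, no drug;
#'   d: condition only).
#' @param excluded Named integer vector of planted exclusion patterns among
#'   `no_condition` (drug and event, never the condition), `prior_drug`
#'   (drug before condition) and `prevalent_event` (event before condition).
#' @param window_start,window_end Date window the planted mentions fall in.
#' @param notes_per_patient Integer range `c(min, max)`: total notes per
#'   patient (raised to the number a patient's pattern requires).
#' @param negation_rate Probability per note of appending a negated decoy
#'   mention of a triplet term.
#' @param fp_noise Probability per note of inserting a spurious lexicon term.
#' @param fn_noise Probability per note of deleting its planted mentions.
#' @param icd9_fraction Probability that a planted condition/event mention
#'   also emits a coded ICD-9 record on the same date.
#' @param seed Integer seed; the corpus is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(cells = c(a = 3, b = 2, c = 2, d = 5),
                         excluded = c(no_condition = 0, prior_drug = 0,
                                      prevalent_event = 0),
                         window_start = "1999-01-01",
                         window_end = "2004-12-31",
                         notes_per_patient = c(1, 3),
                         negation_rate = 0,
                         fp_noise = 0,
                         fn_noise = 0,
                         icd9_fraction = 0,
                         seed = 1L) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(cells)),
            all(cells >= 0),
            all(notes_per_patient >= 1),
            negation_rate >= 0, negation_rate <= 1,
            fp_noise >= 0, fp_noise <= 1,
            fn_noise >= 0, fn_noise <= 1,
            icd9_fraction >= 0, icd9_fraction <= 1)
  excl_full <- c(no_condition = 0, prior_drug = 0, prevalent_event = 0)
  excl_full[names(excluded)] <- excluded
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (as.integer(window_end - window_start) + 1L < 3L) {
    abort("window too narrow to order three distinct dates")
  }
  structure(list(cells = cells[c("a", "b", "c", "d")], excluded = excl_full,
                 window_start = window_start, window_end = window_end,
                 notes_per_patient = as.integer(notes_per_patient),
                 negation_rate = negation_rate, fp_noise = fp_noise,
                 fn_noise = fn_noise, icd9_fraction = icd9_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

mention_templates <- c(
  "Follow-up visit. Patient has a history of %s. Plan discussed.",
  "Assessment: %s noted today. Monitoring to continue.",
  "Clinic note. %s documented during this encounter.",
  "Progress note: patient presents with %s. Medications reviewed."
)

decoy_templates <- c(
  "No evidence of %s at this time.",
  "Patient denies %s.",
  "Negative for %s on review of systems."
)

filler_sentences <- c(
  "Vital signs stable. Patient resting comfortably.",
  "Labs reviewed and discussed with patient.",
  "Patient to return in three months for routine follow-up.",
  "Counseled on diet and exercise."
)

noise_template <- "Also notes %s in recent records."

# surfaces used when planting each triplet role
planted_surfaces <- list(
  cond = "rheumatoid arthritis",
  drug = c("Vioxx", "rofecoxib"),
  evt = "myocardial infarction"
)

# mention roles required by each planted pattern, in temporal order
pattern_roles <- list(
  A = c("cond", "drug", "evt"),
  B = c("cond", "drug"),
  C = c("cond", "evt"),
  D = "cond",
  no_condition = c("drug", "evt"),
  prior_drug = c("drug", "cond"),
  prevalent_event = c("evt", "cond")
)

role_concepts <- c(cond = "C_RA", drug = "C_ROFECOXIB", evt = "C_MI")

#' Generate a synthetic note corpus with planted temporal patterns
#'
#' For every planted cell-a patient the first mentions of the condition, the
#' drug and the event fall on strictly increasing dates within the window;
#' the other cells and the exclusion patterns are planted analogously.
#' Mentions are embedded in clinically flavored filler sentences; decoy
#' negated mentions, spurious insertions and mention dropout are controlled
#' by the config. A parallel ICD-9 record stream is emitted for a
#' configurable fraction of condition/event mentions. Everything is
#' deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return A list with `notes` (tibble: `patient_id`, `note_id`, `note_date`,
#'   `text`), `coded` (tibble: `patient_id`, `date`, `icd9_code`) and `truth`
#'   (list with `patients`: planted label and `mentions`: planted per-note
#'   concept states before noise).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  labels <- c(rep("A", config$cells["a"]), rep("B", config$cells["b"]),
              rep("C", config$cells["c"]), rep("D", config$cells["d"]),
              rep(names(config$excluded), config$excluded))
  days <- seq(config$window_start, config$window_end, by = "day")
  n_pat <- length(labels)
  empty <- list(
    notes = tibble(patient_id = character(), note_id = character(),
                   note_date = as.Date(character()), text = character()),
    coded = tibble(patient_id = character(), date = as.Date(character()),
                   icd9_code = character()),
    truth = list(patients = tibble(patient_id = character(), cell = character()),
                 mentions = tibble(note_id = character(), concept_id = character(),
                                   negated = logical()))
  )
  if (n_pat == 0) return(empty)
  with_rng_seed(config$seed, {
    notes_l <- vector("list", n_pat)
    coded_l <- vector("list", n_pat)
    truth_l <- vector("list", n_pat)
    decoy_surfaces <- unlist(planted_surfaces, use.names = FALSE)
    all_surfaces <- synth_lexicon()$surface
    for (p in seq_len(n_pat)) {
      pid <- sprintf("P%05d", p)
      roles <- pattern_roles[[labels[p]]]
      n_mention <- length(roles)
      n_total <- max(n_mention,
                     sample(config$notes_per_patient[1]:config$notes_per_patient[2], 1))
      dates <- sort(sample(days, n_total, replace = FALSE))
      # mention notes take the earliest dates in role order; fillers follow
      texts <- character(n_total)
      m_concepts <- vector("list", n_total)
      m_negated <- vector("list", n_total)
      for (k in seq_len(n_total)) {
        sentences <- character()
        concepts <- character()
        negated <- logical()
        if (k <= n_mention) {
          role <- roles[k]
          surf <- planted_surfaces[[role]]
          surf <- if (length(surf) > 1) sample(surf, 1) else surf
          tmpl <- sample(mention_templates, 1)
          dropped <- config$fn_noise > 0 && runif(1) < config$fn_noise
          if (!dropped) {
            sentences <- c(sentences, sprintf(tmpl, surf))
            concepts <- c(concepts, role_concepts[[role]])
            negated <- c(negated, FALSE)
          }
          # coded record mirrors the planted mention even when the text copy
          # is dropped by noise (coding is an independent channel)
          if (role %in% c("cond", "evt") && config$icd9_fraction > 0 &&
              runif(1) < config$icd9_fraction) {
            coded_l[[p]] <- bind_rows(coded_l[[p]], tibble(
              patient_id = pid, date = dates[k],
              icd9_code = if (role == "cond") "714.0" else "410.1"))
          }
        } else {
          sentences <- c(sentences, sample(filler_sentences, 1))
        }
        if (config$negation_rate > 0 && runif(1) < config$negation_rate) {
          dsurf <- sample(decoy_surfaces, 1)
          sentences <- c(sentences, sprintf(sample(decoy_templates, 1), dsurf))
        }
        if (config$fp_noise > 0 && runif(1) < config$fp_noise) {
          nsurf <- sample(all_surfaces, 1)
          sentences <- c(sentences, sprintf(noise_template, nsurf))
        }
        if (length(sentences) == 0) {
          sentences <- sample(filler_sentences, 1)
        }
        texts[k] <- paste(sentences, collapse = " ")
        m_concepts[[k]] <- concepts
        m_negated[[k]] <- negated
      }
      note_ids <- sprintf("%s-N%02d", pid, seq_len(n_total))
      notes_l[[p]] <- tibble(patient_id = pid, note_id = note_ids,
                             note_date = dates, text = texts)
      nm <- lengths(m_concepts)
      truth_l[[p]] <- tibble(note_id = rep(note_ids, nm),
                             concept_id = unlist(m_concepts, use.names = FALSE) %||% character(),
                             negated = unlist(m_negated, use.names = FALSE) %||% logical())
    }
    truth_cells <- if_else(labels %in% c("A", "B", "C", "D"), labels, "EXCLUDED")
    out <- list(
      notes = bind_rows(notes_l),
      coded = bind_rows(coded_l) %||% empty$coded,
      truth = list(
        patients = tibble(patient_id = sprintf("P%05d", seq_len(n_pat)),
                          cell = truth_cells, pattern = labels),
        mentions = bind_rows(truth_l)
      )
    )
    if (nrow(out$coded) == 0) out$coded <- empty$coded
    out
  })
}

#' Inject spurious and dropped mentions into a note stream
#'
#' Independently per note: with probability `fp_noise` a spurious lexicon
#' term is appended in a filler sentence; with probability `fn_noise` every
#' sentence containing a lexicon term is deleted. Deterministic given the
#' seed.
#'
#' @param notes Notes tibble (`patient_id`, `note_id`, `note_date`, `text`).
#' @param fp_noise,fn_noise Probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @param lexicon Lexicon tibble supplying the spurious terms and defining
#'   which sentences count as mentions (default [synth_lexicon()]).
#' @return The notes tibble with modified `text`.
#' @export
inject_noise <- function(notes, fp_noise, fn_noise, seed,
                         lexicon = synth_lexicon()) {
  stopifnot(fp_noise >= 0, fp_noise <= 1, fn_noise >= 0, fn_noise <= 1)
  if (nrow(notes) == 0 || (fp_noise == 0 && fn_noise == 0)) return(notes)
  surf_re <- paste0("\\b(", paste(vapply(tolower(lexicon$surface),
                                         function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s),
                                         character(1)), collapse = "|"), ")\\b")
  with_rng_seed(seed, {
    texts <- notes$text
    for (i in seq_along(texts)) {
      if (fn_noise > 0 && runif(1) < fn_noise) {
        sentences <- unlist(strsplit(texts[i], "(?<=[.!?])\\s+", perl = TRUE))
        keep <- !grepl(surf_re, tolower(sentences), perl = TRUE)
        texts[i] <- paste(sentences[keep], collapse = " ")
      }
      if (fp_noise > 0 && runif(1) < fp_noise) {
        surf <- sample(lexicon$surface, 1)
        texts[i] <- trimws(paste(texts[i], sprintf(noise_template, surf)))
      }
    }
    notes$text <- texts
    notes
  })
}

#' Draw one stochastic cohort contingency table from a planted risk model
#'
#' Exposure arms of fixed size; each patient's event indicator is an
#' independent Bernoulli draw with arm-specific probability. The population
#' odds ratio of the model is
#' `(p_exposed / (1 - p_exposed)) / (p_unexposed / (1 - p_unexposed))`.
#'
#' @param n_exposed,n_unexposed Arm sizes.
#' @param p_exposed,p_unexposed Event probabilities per arm.
#' @return A `contingency_table` with the drawn counts.
#' @export
sample_cohort_table <- function(n_exposed, n_unexposed,
                                p_exposed, p_unexposed) {
  a <- rbinom(1, n_exposed, p_exposed)
  c_ <- rbinom(1, n_unexposed, p_unexposed)
  contingency_table(a, n_exposed - a, c_, n_unexposed - c_)
}
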