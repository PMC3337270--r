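#' Define a condition-drug-event triplet query
#'
#' A hypothesized drug-safety signal: a condition (the drug's usual
#' indication, which restricts the background cohort), a drug exposure and an
#' adverse event, tested within a calendar window. The canonical example is
#' rheumatoid arthritis - rofecoxib - myocardial infarction within the
#' 1999-2004 market window.
#'
#' @param condition,drug,event Concept ids (must be pairwise distinct).
#' @param window_start,window_end Inclusive date window (default the
#'   rofecoxib market window 1999-01-01 to 2004-12-31).
#' @return A `triplet_query` object.
#' @export
triplet_query <- function(condition, drug, event,
                          window_start = "1999-01-01",
                          window_end = "2004-12-31") {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start > window_end) abort("window_start must not exceed window_end")
  if (anyDuplicated(c(condition, drug, event))) {
    abort("condition, drug and event concepts must be distinct")
  }
  structure(list(condition = condition, drug = drug, event = event,
                 window_start = window_start, window_end = window_end),
            class = "triplet_query")
}

#' @export
print.triplet_query <- function(x, ...) {
  cat(sprintf("<triplet_query> %s -> %s -> %s in [%s, %s]\n",
              x$condition, x$drug, x$event,
              format(x$window_start), format(x$window_end)))
  invisible(x)
}

#' Classify cohort patients into contingency cells by temporal pattern
#'
#' For each patient the first positive mention date of the condition, the
#' drug and the event determines a cell of the 2x2 table:
#' a patient is *exposed* iff the first drug mention strictly follows the
#' first condition mention; an exposed patient lands in cell A when the first
#' event mention strictly follows the first drug mention, otherwise in B; an
#' unexposed patient lands in C when the first event mention strictly follows
#' the first condition mention, otherwise in D. Patients without any positive
#' condition mention, patients whose first drug mention precedes the
#' condition, and patients whose first event mention precedes the condition
#' are excluded (the latter two policies are configurable). Negated mentions
#' never count as occurrences.
#'
#' @param timelines Event tibble (already window-filtered; see
#'   [filter_window()]).
#' @param triplet A [triplet_query()].
#' @param ties `"strict"` (default): same-day mentions do not establish
#'   temporal succession; `"weak"`: same-day counts as following.
#' @param prior_drug_policy `"exclude"` (default) drops patients whose first
#'   drug mention precedes the first condition mention; `"unexposed"` pools
#'   them into the unexposed arm.
#' @param prevalent_event_policy `"exclude"` (default) drops patients whose
#'   first event mention precedes the first condition mention; `"keep"`
#'   retains them, dating the event from its first occurrence after the
#'   condition.
#' @param icd9_only When `TRUE`, condition and event occurrences are taken
#'   from coded-provenance events only; drug exposure still uses whatever
#'   occurrence channel the timelines carry.
#' @return A tibble with columns `patient_id`, `cell`
#'   (`"A"`, `"B"`, `"C"`, `"D"`, `"EXCLUDED"`) and `reason` (`NA` unless
#'   excluded: `"no_condition"`, `"prior_drug"`, `"prevalent_event"`).
#' @export
classify_patients <- function(timelines, triplet,
                              ties = c("strict", "weak"),
                              prior_drug_policy = c("exclude", "unexposed"),
                              prevalent_event_policy = c("exclude", "keep"),
                              icd9_only = FALSE) {
  ties <- match.arg(ties)
  prior_drug_policy <- match.arg(prior_drug_policy)
  prevalent_event_policy <- match.arg(prevalent_event_policy)
  stopifnot(inherits(triplet, "triplet_query"))
  follows <- if (ties == "strict") `<` else `<=`

  pos <- filter(timelines, .data$state == "positive")
  cond_ev <- filter(pos, .data$concept_id == triplet$condition,
                    !icd9_only | .data$provenance == "coded")
  evt_ev <- filter(pos, .data$concept_id == triplet$event,
                   !icd9_only | .data$provenance == "coded")
  drug_ev <- filter(pos, .data$concept_id == triplet$drug)

  pats <- unique(timelines$patient_id)
  first_date <- function(ev) {
    if (nrow(ev) == 0) return(rep(as.Date(NA), length(pats)))
    s <- ev %>% group_by(.data$patient_id) %>%
      summarise(t = min(.data$timestamp), .groups = "drop")
    s$t[match(pats, s$patient_id)]
  }
  t_cond <- first_date(cond_ev)
  t_drug <- first_date(drug_ev)
  t_evt <- first_date(evt_ev)

  # event dates per patient, for the "first event after X" variants
  evt_by_pat <- split(evt_ev$timestamp, evt_ev$patient_id)
  first_evt_after <- function(pid, t0) {
    d <- evt_by_pat[[pid]]
    d <- d[follows(t0, d)]
    if (length(d)) min(d) else as.Date(NA)
  }

  n <- length(pats)
  cell <- character(n)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    tc <- t_cond[k]
    td <- t_drug[k]
    te <- t_evt[k]
    if (is.na(tc)) {
      cell[k] <- "EXCLUDED"
      reason[k] <- "no_condition"
      next
    }
    if (!is.na(td) && td < tc && prior_drug_policy == "exclude") {
      cell[k] <- "EXCLUDED"
      reason[k] <- "prior_drug"
      next
    }
    if (!is.na(te) && te < tc) {
      if (prevalent_event_policy == "exclude") {
        cell[k] <- "EXCLUDED"
        reason[k] <- "prevalent_event"
        next
      }
      te <- first_evt_after(pats[k], tc)
    }
    exposed <- !is.na(td) && follows(tc, td)
    if (exposed) {
      cell[k] <- if (!is.na(te) && follows(td, te)) "A" else "B"
    } else {
      cell[k] <- if (!is.na(te) && follows(tc, te)) "C" else "D"
    }
  }
  tibble(patient_id = pats, cell = cell, reason = reason)
}

#' Construct a 2x2 contingency table
#'
#' Cells follow the exposure-by-event convention: `a` exposed with event,
#' `b` exposed without, `c` unexposed with event, `d` unexposed without,
#' all within the indication cohort.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param excluded Optional named integer vector of excluded-patient counts.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d, excluded = integer()) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), excluded = excluded),
            class = "contingency_table")
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    return(contingency_table(x[1], x[2], x[3], x[4]))
  }
  abort("expected a contingency_table or a numeric vector of 4 cells")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  if (length(x$excluded) && sum(x$excluded) > 0) {
    cat("excluded:", paste(names(x$excluded), x$excluded, sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count classified patients into a contingency table
#'
#' @param timelines Window-filtered event tibble.
#' @param triplet A [triplet_query()].
#' @param ... Policy arguments passed to [classify_patients()].
#' @return A `contingency_table` with per-reason excluded counts.
#' @export
build_contingency <- function(timelines, triplet, ...) {
  cls <- classify_patients(timelines, triplet, ...)
  nof <- function(x) sum(cls$cell == x)
  excl <- cls[cls$cell == "EXCLUDED", ]
  excluded <- table(factor(excl$reason,
                           levels = c("no_condition", "prior_drug",
                                      "prevalent_event")))
  contingency_table(nof("A"), nof("B"), nof("C"), nof("D"),
                    excluded = setNames(as.integer(excluded), names(excluded)))
}

#' Test a condition-drug-event safety signal end to end
#'
#' Runs the full analysis for one triplet: select the cohort of patients
#' positively mentioning any of the three concepts, build timelines (merging
#' coded ICD-9 events when supplied), restrict to the query window, classify
#' each patient by the temporal ordering of first mentions, count the 2x2
#' table, and compute the odds ratio, Woolf confidence interval and
#' two-sided Fisher exact p-value.
#'
#' @param matrix An `ade_matrix` from [build_feature_matrix()].
#' @param triplet A [triplet_query()].
#' @param coded Optional coded-event tibble from [ingest_icd9()].
#' @param ties,prior_drug_policy,prevalent_event_policy,icd9_only Passed to
#'   [classify_patients()]. With `icd9_only = TRUE` the condition and event
#'   channels are restricted to coded-provenance events while drug exposure
#'   uses the occurrence channel supplied to the run.
#' @param level Confidence level for the Woolf interval (default 0.95).
#' @return A `signal_result` object (see [tidy.signal_result()]).
#' @export
test_signal <- function(matrix, triplet, coded = NULL,
                        ties = "strict",
                        prior_drug_policy = "exclude",
                        prevalent_event_policy = "exclude",
                        icd9_only = FALSE, level = 0.95) {
  stopifnot(inherits(triplet, "triplet_query"))
  tl <- build_timelines(matrix, coded)
  tl <- select_cohort(tl, c(triplet$condition, triplet$drug, triplet$event))
  tl <- filter_window(tl, triplet$window_start, triplet$window_end)
  tab <- build_contingency(tl, triplet, ties = ties,
                           prior_drug_policy = prior_drug_policy,
                           prevalent_event_policy = prevalent_event_policy,
                           icd9_only = icd9_only)
  config <- list(
    condition = triplet$condition, drug = triplet$drug, event = triplet$event,
    window_start = format(triplet$window_start),
    window_end = format(triplet$window_end),
    ties = ties, prior_drug_policy = prior_drug_policy,
    prevalent_event_policy = prevalent_event_policy,
    icd9_only = icd9_only, level = level
  )
  signal_result(tab, level = level, config = config)
}
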