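new_ade_matrix <- function(rows, cells) {
  structure(list(rows = rows, cells = cells), class = "ade_matrix")
}

#' Build the note-by-concept patient feature matrix
#'
#' One row per clinical note; sparse cells record, per concept, whether the
#' note mentions it positively or only negated (absent cells are simply not
#' stored). Duplicate `note_id`s are rejected: the first occurrence wins and
#' later ones are dropped with a warning.
#'
#' @param annotated Output of [annotate_notes()].
#' @param notes Optional original notes tibble; when supplied, notes without
#'   any annotation still contribute (empty) matrix rows.
#' @return An `ade_matrix`: a list with tibbles `rows` (`note_id`,
#'   `patient_id`, `note_date`) and `cells` (`note_id`, `concept_id`, `state`
#'   with state `"positive"` or `"negated"`).
#' @export
build_feature_matrix <- function(annotated, notes = NULL) {
  ann <- as_tibble(annotated)
  if (!is.null(notes)) {
    rows <- tibble(note_id = as.character(notes$note_id),
                   patient_id = as.character(notes$patient_id),
                   note_date = as_date_strict(notes$note_date, "note_date"))
    rows <- rows[!is.na(rows$note_date), , drop = FALSE]
  } else {
    rows <- distinct(ann[, c("note_id", "patient_id", "note_date")])
  }
  dup <- duplicated(rows$note_id)
  if (any(dup)) {
    warn(sprintf("rejected %d duplicate note row(s)", sum(dup)))
    rows <- rows[!dup, , drop = FALSE]
  }
  rows <- arrange(rows, .data$patient_id, .data$note_date, .data$note_id)
  cells <- ann %>%
    filter(.data$note_id %in% rows$note_id) %>%
    mutate(state = if_else(.data$negated, "negated", "positive")) %>%
    select("note_id", "concept_id", "state") %>%
    distinct() %>%
    arrange(.data$note_id, .data$concept_id)
  new_ade_matrix(rows = rows, cells = cells)
}

#' @export
print.ade_matrix <- function(x, ...) {
  cat(sprintf("<ade_matrix> %d notes x %d concepts (%d stored cells, %d patients)\n",
              nrow(x$rows), dplyr::n_distinct(x$cells$concept_id),
              nrow(x$cells), dplyr::n_distinct(x$rows$patient_id)))
  invisible(x)
}

#' Tidy a feature matrix into one row per stored cell
#'
#' @param x An `ade_matrix` from [build_feature_matrix()].
#' @param ... Unused.
#' @return A tibble with `note_id`, `patient_id`, `note_date`, `concept_id`,
#'   `state`.
#' @method tidy ade_matrix
#' @export
tidy.ade_matrix <- function(x, ...) {
  left_join(x$cells, x$rows, by = "note_id") %>%
    select("note_id", "patient_id", "note_date", "concept_id", "state")
}

#' Map coded ICD-9 records onto concepts by code prefix
#'
#' A record maps to a concept iff its code string starts with one of the
#' mapped prefixes; when several prefixes match, the longest wins. Codes with
#' no matching prefix are dropped (their count is reported in a message).
#' Rheumatoid arthritis codes begin with 714 and myocardial infarction codes
#' with 410, so a typical map is `{"714" -> C_RA, "410" -> C_MI}`.
#'
#' @param records Tibble from [read_icd9()] (`patient_id`, `date`,
#'   `icd9_code`).
#' @param code_map Tibble with columns `prefix`, `concept_id`, or a named
#'   character vector `c("714" = "C_RA", ...)`.
#' @return A tibble with columns `patient_id`, `date`, `concept_id`,
#'   `state = "positive"`, `provenance = "coded"`.
#' @export
ingest_icd9 <- function(records, code_map) {
  if (!is.data.frame(code_map)) {
    code_map <- tibble(prefix = names(code_map),
                       concept_id = unname(code_map))
  }
  stopifnot(all(nzchar(code_map$prefix)))
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  concept_id = character(), state = character(),
                  provenance = character()))
  }
  # longest matching prefix wins
  ord <- order(-nchar(code_map$prefix))
  code_map <- code_map[ord, , drop = FALSE]
  concept <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(code_map))) {
    hit <- is.na(concept) & startsWith(records$icd9_code, code_map$prefix[i])
    concept[hit] <- code_map$concept_id[i]
  }
  n_drop <- sum(is.na(concept))
  if (n_drop > 0) {
    inform(sprintf("dropped %d ICD-9 record(s) with unmapped codes", n_drop))
  }
  keep <- !is.na(concept)
  tibble(patient_id = as.character(records$patient_id[keep]),
         date = as.Date(records$date[keep]),
         concept_id = concept[keep],
         state = "positive",
         provenance = "coded")
}

#' Assemble per-patient temporally ordered event timelines
#'
#' Merges note-derived concept states with coded ICD-9 events into one event
#' stream per patient, sorted by date. On date ties, note events precede
#' coded events, and notes are ordered by `note_id`; day is the finest time
#' resolution carried by the data.
#'
#' @param matrix An `ade_matrix` from [build_feature_matrix()].
#' @param coded Optional tibble from [ingest_icd9()].
#' @return A tibble of events with columns `patient_id`, `timestamp` (Date),
#'   `concept_id`, `state`, `provenance` (`"note"` or `"coded"`), `note_id`
#'   (`NA` for coded events), sorted within each patient.
#' @export
build_timelines <- function(matrix, coded = NULL) {
  note_ev <- tidy.ade_matrix(matrix) %>%
    mutate(provenance = "note") %>%
    rename(timestamp = "note_date")
  note_ev <- note_ev[, c("patient_id", "timestamp", "concept_id", "state",
                         "provenance", "note_id")]
  if (!is.null(coded) && nrow(coded) > 0) {
    coded_ev <- tibble(patient_id = as.character(coded$patient_id),
                       timestamp = as.Date(coded$date),
                       concept_id = coded$concept_id,
                       state = coded$state,
                       provenance = coded$provenance,
                       note_id = NA_character_)
    ev <- bind_rows(note_ev, coded_ev)
  } else {
    ev <- note_ev
  }
  ev %>%
    mutate(.prov_rank = if_else(.data$provenance == "note", 0L, 1L)) %>%
    arrange(.data$patient_id, .data$timestamp, .data$.prov_rank,
            .data$note_id, .data$concept_id) %>%
    select(-".prov_rank")
}

#' Restrict timelines to patients positively mentioning given concepts
#'
#' Retains every patient with at least one positive (non-negated) occurrence
#' of any concept in `concepts`; kept timelines are unmodified. Negated
#' mentions never qualify a patient.
#'
#' @param timelines Event tibble from [build_timelines()].
#' @param concepts Non-empty character vector of concept ids.
#' @return The filtered event tibble.
#' @export
select_cohort <- function(timelines, concepts) {
  stopifnot(length(concepts) > 0)
  keep <- timelines %>%
    filter(.data$state == "positive", .data$concept_id %in% concepts) %>%
    distinct(.data$patient_id)
  semi_join(timelines, keep, by = "patient_id")
}

#' Restrict timelines to a date window
#'
#' Keeps events with `window_start <= timestamp <= window_end`; patients left
#' with no events simply disappear from downstream counting. The default
#' market window for the rofecoxib analysis is 1999-01-01 to 2004-12-31.
#'
#' @param timelines Event tibble from [build_timelines()].
#' @param window_start,window_end Dates (inclusive bounds).
#' @return The filtered event tibble.
#' @export
filter_window <- function(timelines, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end)
  filter(timelines, .data$timestamp >= window_start,
         .data$timestamp <= window_end)
}

#' Plot patient timelines
#'
#' One horizontal track per patient; points mark concept events, colored by
#' concept, shaped by provenance, hollow when negated.
#'
#' @param timelines Event tibble from [build_timelines()].
#' @param patients Optional patient ids to show (default: first 20).
#' @return A ggplot object.
#' @export
plot_timelines <- function(timelines, patients = NULL) {
  if (is.null(patients)) {
    patients <- head(unique(timelines$patient_id), 20)
  }
  df <- filter(timelines, .data$patient_id %in% patients)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$patient_id,
                                   color = .data$concept_id,
                                   shape = .data$provenance,
                                   alpha = .data$state)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_alpha_manual(values = c(positive = 1, negated = 0.35)) +
    ggplot2::labs(x = NULL, y = "patient", color = "concept",
                  shape = "provenance", alpha = "state") +
    ggplot2::theme_minimal()
}
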