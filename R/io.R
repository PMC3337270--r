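#' Read clinical notes from JSON-lines or CSV
#'
#' The JSON-lines form has one object per line with fields `patient_id`,
#' `note_id`, `note_date` (ISO-8601) and `text`; the CSV form has the same
#' columns with a header. Format is inferred from the file extension
#' (`.jsonl`/`.ndjson` vs `.csv`) unless given explicitly.
#'
#' @param path Input file (UTF-8).
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (default).
#' @return A tibble with columns `patient_id`, `note_id`, `note_date` (Date),
#'   `text`.
#' @export
read_notes <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("notes file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path)) "jsonl" else "csv"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    n_bad <- 0L
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$patient_id) || is.null(rec$note_id)) {
        n_bad <- n_bad + 1L
        next
      }
      recs[[i]] <- tibble(
        patient_id = as.character(rec$patient_id),
        note_id = as.character(rec$note_id),
        note_date = as.character(rec$note_date %||% NA_character_),
        text = as.character(rec$text %||% "")
      )
    }
    if (n_bad > 0) warn(sprintf("skipped %d unparseable note line(s)", n_bad))
    out <- bind_rows(recs)
    if (nrow(out) == 0) {
      out <- tibble(patient_id = character(), note_id = character(),
                    note_date = character(), text = character())
    }
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  out$note_date <- as_date_strict(out$note_date, "note_date")
  as_tibble(out[, c("patient_id", "note_id", "note_date", "text")])
}

#' Write clinical notes as JSON-lines
#'
#' @param notes Tibble with `patient_id`, `note_id`, `note_date`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(
      patient_id = notes$patient_id[i],
      note_id = notes$note_id[i],
      note_date = format(as.Date(notes$note_date[i])),
      text = notes$text[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read coded ICD-9 diagnosis records
#'
#' @param path CSV with header columns `patient_id`, `date`, `icd9_code`.
#' @return A tibble with those columns (`date` as `Date`); records with
#'   unparseable dates are dropped with a warning.
#' @export
read_icd9 <- function(path) {
  if (!file.exists(path)) abort(sprintf("ICD-9 file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("patient_id", "date", "icd9_code")
  if (!all(need %in% names(x))) {
    abort(paste0("ICD-9 input needs columns: ", paste(need, collapse = ", ")))
  }
  x$date <- as_date_strict(x$date, "icd9 date")
  bad <- is.na(x$date)
  if (any(bad)) {
    warn(sprintf("dropped %d ICD-9 record(s) with unparseable dates", sum(bad)))
    x <- x[!bad, , drop = FALSE]
  }
  as_tibble(x[, need])
}

#' Serialize a patient feature matrix to coordinate text files
#'
#' Writes the sparse cells as a three-column TSV (`note_id`, `concept_id`,
#' `state`) and the row metadata (`note_id`, `patient_id`, `note_date`) as a
#' sidecar TSV, so notes without any annotated concept are preserved. The
#' round trip through [read_feature_matrix()] is lossless.
#'
#' @param matrix An `ade_matrix` from [build_feature_matrix()].
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_feature_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "ade_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells_path <- file.path(dir, "matrix_cells.tsv")
  rows_path <- file.path(dir, "matrix_rows.tsv")
  readr::write_tsv(matrix$cells, cells_path, progress = FALSE)
  rows <- matrix$rows
  rows$note_date <- format(rows$note_date)
  readr::write_tsv(rows, rows_path, progress = FALSE)
  invisible(c(cells = cells_path, rows = rows_path))
}

#' Load a patient feature matrix written by [write_feature_matrix()]
#'
#' @param dir Directory containing `matrix_cells.tsv` and `matrix_rows.tsv`.
#' @return An `ade_matrix` object.
#' @export
read_feature_matrix <- function(dir) {
  cells_path <- file.path(dir, "matrix_cells.tsv")
  rows_path <- file.path(dir, "matrix_rows.tsv")
  if (!file.exists(cells_path) || !file.exists(rows_path)) {
    abort(sprintf("no feature matrix found under %s", dir))
  }
  cells <- readr::read_tsv(cells_path, col_types = "ccc", progress = FALSE)
  rows <- readr::read_tsv(rows_path, col_types = "ccD", progress = FALSE)
  new_ade_matrix(rows = as_tibble(rows), cells = as_tibble(cells))
}

#' Write a signal test result as a JSON report
#'
#' @param result A `signal_result` from [test_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_report <- function(result, path) {
  stopifnot(inherits(result, "signal_result"))
  report <- list(
    table = list(a = result$table$a, b = result$table$b,
                 c = result$table$c, d = result$table$d),
    excluded = as.list(result$excluded),
    odds_ratio = result$estimate,
    ci_low = result$conf.low,
    ci_high = result$conf.high,
    p_value = result$p.value,
    level = result$level,
    flags = as.list(result$flags),
    config = result$config
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a signal report against the shipped schema
#'
#' Structural validation: required fields present with the expected JSON
#' types, as described by `inst/extdata/signal_report_schema.json`.
#'
#' @param path Path to a JSON report from [write_signal_report()].
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_signal_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("table", "excluded", "odds_ratio", "ci_low", "ci_high",
            "p_value", "level", "flags", "config")
  missing_f <- setdiff(need, names(rep))
  if (length(missing_f)) {
    abort(paste0("report lacks field(s): ", paste(missing_f, collapse = ", ")))
  }
  cells <- c("a", "b", "c", "d")
  if (!all(cells %in% names(rep$table))) abort("report table lacks cells a-d")
  vals <- unlist(rep$table[cells])
  if (!is.numeric(vals) || any(vals < 0) || any(vals != floor(vals))) {
    abort("table cells must be non-negative integers")
  }
  if (!is.numeric(rep$level) || rep$level <= 0 || rep$level >= 1) {
    abort("level must be in (0, 1)")
  }
  invisible(TRUE)
}
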