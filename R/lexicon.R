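#' Read a term lexicon from a tab-delimited file
#'
#' The lexicon maps surface strings (terms as they appear in text) to concept
#' identifiers. Each row of the input is `surface<TAB>concept_id[<TAB>source]`.
#' Surfaces are stored case-preserved; matching downstream is case-insensitive.
#' Duplicate `(surface, concept_id)` pairs are collapsed, and surfaces shorter
#' than `min_chars` characters are dropped unless whitelisted (short
#' abbreviations such as "RA" are high-noise in clinical text).
#'
#' @param path Path to a tab-delimited file with columns
#'   `surface`, `concept_id` and optionally `source`. A header line is not
#'   expected.
#' @param min_chars Minimum surface length in characters (default 3). Shorter
#'   terms are excluded unless listed in `whitelist`.
#' @param whitelist Character vector of short surfaces to retain regardless of
#'   `min_chars` (matched case-insensitively).
#' @return A tibble with columns `surface`, `concept_id`, `source`, one row per
#'   unique `(surface, concept_id)` pair.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("rheumatoid arthritis\tC_RA\tDEMO",
#'              "Vioxx\tC_VIOXX\tDEMO"), tf)
#' read_lexicon(tf)
#' @export
read_lexicon <- function(path, min_chars = 3, whitelist = character()) {
  if (!file.exists(path)) {
    abort(sprintf("lexicon file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn("empty lexicon file; returning an empty lexicon")
    return(tibble(surface = character(), concept_id = character(),
                  source = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 2 && nzchar(trimws(p[1])) && nzchar(trimws(p[2]))
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("skipped %d malformed lexicon row(s)", sum(!ok)))
  }
  parts <- parts[ok]
  lex <- tibble(
    surface = trimws(vapply(parts, `[`, character(1), 1)),
    concept_id = trimws(vapply(parts, `[`, character(1), 2)),
    source = trimws(vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else NA_character_
    }, character(1)))
  )
  lex <- distinct(lex, .data$surface, .data$concept_id, .keep_all = TRUE)
  keep <- nchar(lex$surface) >= min_chars |
    tolower(lex$surface) %in% tolower(whitelist)
  if (any(!keep)) {
    inform(sprintf("dropped %d term(s) shorter than %d characters",
                   sum(!keep), min_chars))
  }
  lex <- lex[keep, , drop = FALSE]
  inform(sprintf("lexicon: %d unique terms, %d concepts",
                 nrow(lex), dplyr::n_distinct(lex$concept_id)))
  lex
}

#' Read a concept-normalization mapping
#'
#' Each row maps a concept id onto its canonical concept id, e.g. the trade
#' name concept for Vioxx onto its active-ingredient concept rofecoxib.
#'
#' @param path Tab-delimited file with two columns: `concept_id`,
#'   `canonical_id` (no header).
#' @return A tibble with columns `concept_id`, `canonical_id`.
#' @export
read_concept_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("mapping file not found: %s", path))
  m <- readr::read_tsv(path, col_names = c("concept_id", "canonical_id"),
                       col_types = "cc", progress = FALSE)
  distinct(as_tibble(m))
}

# Transitively close a concept mapping; abort on cycles.
close_concept_map <- function(map) {
  if (nrow(map) == 0) return(map)
  env <- new.env(parent = emptyenv(), size = nrow(map) * 2L)
  for (i in seq_len(nrow(map))) assign(map$concept_id[i], map$canonical_id[i], envir = env)
  resolve <- function(id) {
    seen <- character()
    cur <- id
    while (!is.null(nxt <- env[[cur]]) && nxt != cur) {
      if (cur %in% seen) {
        abort(sprintf("cyclic normalization mapping: %s",
                      paste(c(seen, cur), collapse = " -> ")))
      }
      seen <- c(seen, cur)
      cur <- nxt
    }
    cur
  }
  tibble(concept_id = map$concept_id,
         canonical_id = vapply(map$concept_id, resolve, character(1)))
}

#' Apply concept normalization to a lexicon
#'
#' Re-points every term whose concept id appears in the mapping onto the
#' mapped canonical id. The mapping is transitively closed before application
#' (a chain A -> B -> C sends terms on A to C), so applying the result twice
#' changes nothing. The number of distinct concepts never increases.
#'
#' @param lexicon A lexicon tibble from [read_lexicon()].
#' @param map A mapping tibble from [read_concept_map()], or a path to one.
#' @return The lexicon tibble with normalized `concept_id`s.
#' @examples
#' lex <- tibble::tibble(surface = "Vioxx", concept_id = "C_VIOXX",
#'                       source = NA_character_)
#' map <- tibble::tibble(concept_id = "C_VIOXX", canonical_id = "C_ROFECOXIB")
#' normalize_lexicon(lex, map)
#' @export
normalize_lexicon <- function(lexicon, map) {
  if (is.character(map) && length(map) == 1) map <- read_concept_map(map)
  if (nrow(map) == 0) return(lexicon)
  closed <- close_concept_map(map)
  idx <- match(lexicon$concept_id, closed$concept_id)
  hit <- !is.na(idx)
  lexicon$concept_id[hit] <- closed$canonical_id[idx[hit]]
  distinct(lexicon, .data$surface, .data$concept_id, .keep_all = TRUE)
}

#' Read a concept hierarchy edge list
#'
#' @param path Tab-delimited file with two columns: `child_id`, `parent_id`
#'   (no header).
#' @return A tibble with columns `child_id`, `parent_id`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) abort(sprintf("hierarchy file not found: %s", path))
  h <- readr::read_tsv(path, col_names = c("child_id", "parent_id"),
                       col_types = "cc", progress = FALSE)
  distinct(as_tibble(h))
}

#' Expand a concept to itself plus all its descendants
#'
#' Subsumption expansion: a cohort query for rheumatoid arthritis may also
#' admit patients annotated with subtypes such as Caplan's or Felty's
#' syndrome. This reasoning is off by default throughout the pipeline and must
#' be enabled explicitly.
#'
#' @param hierarchy A tibble of `(child_id, parent_id)` edges, e.g. from
#'   [read_hierarchy()].
#' @param concept A single concept id.
#' @return Character vector: `concept` plus all transitive descendants.
#' @export
concept_descendants <- function(hierarchy, concept) {
  stopifnot(length(concept) == 1)
  if (!concept %in% c(hierarchy$child_id, hierarchy$parent_id)) {
    warn(sprintf("concept %s not present in hierarchy; returning it alone", concept))
    return(concept)
  }
  out <- concept
  frontier <- concept
  while (length(frontier) > 0) {
    kids <- hierarchy$child_id[hierarchy$parent_id %in% frontier]
    kids <- setdiff(unique(kids), out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Read an OBO 1.2 ontology file into a lexicon and hierarchy
#'
#' A minimal adapter for the standard `[Term]` stanza format: `id`, `name`,
#' `synonym` and `is_a` lines populate the same lexicon/hierarchy tibbles the
#' tab-delimited readers produce. Obsolete terms are skipped.
#'
#' @param path Path to an OBO file.
#' @param source Label recorded in the lexicon `source` column.
#' @return A list with elements `lexicon` (tibble: surface, concept_id,
#'   source) and `hierarchy` (tibble: child_id, parent_id).
#' @export
read_obo <- function(path, source = "OBO") {
  if (!file.exists(path)) abort(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    surfaces <- unique(c(cur$name, cur$synonyms))
    surfaces <- surfaces[nzchar(surfaces)]
    list(
      terms = tibble(surface = surfaces, concept_id = cur$id, source = source),
      edges = if (length(cur$parents))
        tibble(child_id = cur$id, parent_id = cur$parents)
    )
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      res <- flush(cur)
      if (!is.null(res)) {
        terms[[length(terms) + 1L]] <- res$terms
        if (!is.null(res$edges)) edges[[length(edges) + 1L]] <- res$edges
      }
      cur <- list(synonyms = character(), parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      res <- flush(cur)
      if (!is.null(res)) {
        terms[[length(terms) + 1L]] <- res$terms
        if (!is.null(res$edges)) edges[[length(edges) + 1L]] <- res$edges
      }
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && !is.null(cur)) {
      if (grepl("^id:", ln)) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (grepl("^name:", ln)) {
        cur$name <- trimws(sub("^name:", "", ln))
      } else if (grepl("^synonym:", ln)) {
        syn <- stringr::str_match(ln, '^synonym:\\s*"([^"]*)"')[, 2]
        if (!is.na(syn)) cur$synonyms <- c(cur$synonyms, syn)
      } else if (grepl("^is_a:", ln)) {
        parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (nzchar(parent)) cur$parents <- c(cur$parents, parent)
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        cur$obsolete <- TRUE
      }
    }
  }
  res <- flush(cur)
  if (!is.null(res)) {
    terms[[length(terms) + 1L]] <- res$terms
    if (!is.null(res$edges)) edges[[length(edges) + 1L]] <- res$edges
  }
  list(
    lexicon = if (length(terms)) distinct(bind_rows(terms)) else
      tibble(surface = character(), concept_id = character(), source = character()),
    hierarchy = if (length(edges)) distinct(bind_rows(edges)) else
      tibble(child_id = character(), parent_id = character())
  )
}
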