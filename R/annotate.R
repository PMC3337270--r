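#' Tokenize text into alphanumeric tokens with character offsets
#'
#' Tokens are maximal runs of alphanumeric characters. Offsets are 0-based
#' half-open into the original string, so `substr(text, start + 1, end)`
#' recovers each token.
#'
#' @param text A single character string.
#' @return A tibble with columns `token`, `start`, `end`.
#' @examples
#' tokenize("no MI.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble(token = substring(text, start + 1L, end), start = start, end = end)
}

# Multi-token hash index over lowercased token sequences: key is the phrase's
# tokens joined by single spaces; value is the sorted set of concept ids.
term_index <- function(surfaces, concept_ids) {
  keys <- phrase_key(surfaces)
  keep <- which(nzchar(keys))
  env <- new.env(parent = emptyenv(), size = max(length(keep) * 2L, 16L))
  maxlen <- 1L
  for (i in keep) {
    k <- keys[i]
    nl <- lengths(strsplit(k, " ", fixed = TRUE))
    maxlen <- max(maxlen, nl)
    env[[k]] <- sort(unique(c(env[[k]], concept_ids[i])))
  }
  list(env = env, maxlen = as.integer(maxlen))
}

# Enumerate all token-aligned index hits in a token sequence.
# Returns parallel vectors of first/last token index and the matched key.
scan_tokens <- function(toks, idx) {
  n <- length(toks)
  hits_i <- integer()
  hits_j <- integer()
  hits_key <- character()
  if (n == 0L || idx$maxlen < 1L) {
    return(list(i = hits_i, j = hits_j, key = hits_key))
  }
  env <- idx$env
  maxlen <- idx$maxlen
  for (i in seq_len(n)) {
    key <- toks[i]
    upper <- min(maxlen, n - i + 1L)
    for (len in seq_len(upper)) {
      if (len > 1L) key <- paste(key, toks[i + len - 1L])
      if (!is.null(env[[key]])) {
        hits_i <- c(hits_i, i)
        hits_j <- c(hits_j, i + len - 1L)
        hits_key <- c(hits_key, key)
      }
    }
  }
  list(i = hits_i, j = hits_j, key = hits_key)
}

# Overlap resolution: longest character span wins, ties by leftmost start.
# Returns indices into the candidate vectors, ordered by start offset.
select_spans <- function(cs, ce) {
  if (length(cs) == 0L) return(integer())
  ord <- order(-(ce - cs), cs)
  chosen <- integer()
  for (k in ord) {
    if (!any(cs[k] < ce[chosen] & ce[k] > cs[chosen])) chosen <- c(chosen, k)
  }
  chosen[order(cs[chosen])]
}

#' Match lexicon terms in a note's text
#'
#' Case-insensitive, token-boundary-aligned dictionary matching. All candidate
#' matches are enumerated with a multi-token hash automaton over the
#' lowercased token sequence; overlaps are resolved longest-match-first with
#' ties broken by leftmost start. A surface mapped to several concepts yields
#' one annotation per concept on the same span.
#'
#' @param text A single character string (the note text), or a one-row tibble
#'   with a `text` column.
#' @param lexicon A lexicon tibble (columns `surface`, `concept_id`), or a
#'   prebuilt index from the internal matcher.
#' @param across_lines If `FALSE` (default) a multi-token term never matches
#'   across a newline.
#' @return A tibble with columns `concept_id`, `start`, `end` (0-based
#'   half-open character offsets), `surface` (the covered text) and `negated`
#'   (all `FALSE`; see [detect_negation()]), ordered by `start` then
#'   `concept_id`.
#' @examples
#' lex <- tibble::tibble(surface = c("arthritis", "rheumatoid arthritis"),
#'                       concept_id = c("C_ART", "C_RA"))
#' match_terms("history of rheumatoid arthritis", lex)
#' @export
match_terms <- function(text, lexicon, across_lines = FALSE) {
  if (is.data.frame(text)) {
    stopifnot(nrow(text) == 1)
    text <- text$text
  }
  stopifnot(is.character(text), length(text) == 1)
  idx <- term_index(lexicon$surface, lexicon$concept_id)
  tk <- tokenize(text)
  ann <- match_tokens(tolower(tk$token), tk$start, tk$end, text, idx, across_lines)
  surf <- if (length(ann$start)) substring(text, ann$start + 1L, ann$end) else character()
  tibble(concept_id = ann$concept_id, start = ann$start, end = ann$end,
         surface = surf,
         negated = FALSE) %>%
    arrange(.data$start, .data$concept_id)
}

# Core matcher on pre-tokenized input. Returns concept/span vectors plus the
# token range of each annotation (needed by negation scoping).
match_tokens <- function(toks, starts, ends, text, idx, across_lines) {
  empty <- list(concept_id = character(), start = integer(), end = integer(),
                ti = integer(), tj = integer())
  hits <- scan_tokens(toks, idx)
  if (length(hits$i) == 0L) return(empty)
  cs <- starts[hits$i]
  ce <- ends[hits$j]
  if (!across_lines) {
    multi <- hits$j > hits$i
    if (any(multi)) {
      spans <- substring(text, cs + 1L, ce)
      drop <- multi & grepl("\n", spans, fixed = TRUE)
      if (any(drop)) {
        hits <- lapply(hits, `[`, !drop)
        cs <- cs[!drop]
        ce <- ce[!drop]
      }
    }
  }
  if (length(hits$i) == 0L) return(empty)
  sel <- select_spans(cs, ce)
  concepts <- lapply(sel, function(k) idx$env[[hits$key[k]]])
  reps <- lengths(concepts)
  list(concept_id = unlist(concepts, use.names = FALSE) %||% character(),
       start = rep(cs[sel], reps),
       end = rep(ce[sel], reps),
       ti = rep(hits$i[sel], reps),
       tj = rep(hits$j[sel], reps))
}

build_trigger_indexes <- function(triggers) {
  stopifnot(inherits(triggers, "trigger_set"))
  mk <- function(phr) term_index(phr, phrase_key(phr))
  list(pre = mk(triggers$pre), post = mk(triggers$post),
       pseudo = mk(triggers$pseudo), term = mk(triggers$term),
       window = triggers$scope_window)
}

# Negation flags for annotation token ranges [ti, tj] within one note.
# A span is negated iff a surviving pre-trigger precedes it, or a post-trigger
# follows it, within the scope window, with no sentence boundary or
# termination phrase in between. Pseudo-negation phrases swallow the triggers
# they contain.
negation_flags <- function(toks, starts, ends, text, ti, tj, trig) {
  nspan <- length(ti)
  if (nspan == 0L) return(logical())
  occ <- function(ix) scan_tokens(toks, ix)
  pre <- occ(trig$pre)
  post <- occ(trig$post)
  pseudo <- occ(trig$pseudo)
  term <- occ(trig$term)
  surviving <- function(o) {
    if (length(o$i) == 0L || length(pseudo$i) == 0L) return(o)
    keep <- !vapply(seq_along(o$i), function(k) {
      any(pseudo$i <= o$i[k] & o$j[k] <= pseudo$j)
    }, logical(1))
    lapply(o, `[`, keep)
  }
  pre <- surviving(pre)
  post <- surviving(post)
  bm <- gregexpr("[.;:!?\n]", text)[[1]]
  bpos <- if (bm[1] == -1) integer() else as.integer(bm) - 1L  # 0-based
  boundary_between <- function(c1, c2) any(bpos >= c1 & bpos < c2)
  term_between <- function(t1, t2) {
    length(term$i) > 0L && any(term$i > t1 & term$j < t2)
  }
  W <- trig$window
  vapply(seq_len(nspan), function(k) {
    a1 <- ti[k]
    a2 <- tj[k]
    pre_hit <- FALSE
    for (q in seq_along(pre$i)) {
      p2 <- pre$j[q]
      if (p2 < a1 && a1 - p2 <= W &&
          !boundary_between(ends[p2], starts[a1]) &&
          !term_between(p2, a1)) {
        pre_hit <- TRUE
        break
      }
    }
    if (pre_hit) return(TRUE)
    for (q in seq_along(post$i)) {
      p1 <- post$i[q]
      if (p1 > a2 && p1 - a2 <= W &&
          !boundary_between(ends[a2], starts[p1]) &&
          !term_between(a2, p1)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' Flag negated annotations with NegEx-style trigger rules
#'
#' A mention is flagged negated iff a pre-negation trigger precedes it within
#' the trigger set's scope window, or a post-negation trigger follows it
#' within that window; the scope is truncated by sentence boundaries
#' (`.;:!?` and newline) and by termination phrases ("but", "however", ...).
#' Pseudo-negation phrases ("no increase") never negate and mask the trigger
#' words they contain. Spans and concepts are never altered, only the
#' `negated` flag.
#'
#' @param text The note text the annotations were produced from.
#' @param annotations A tibble from [match_terms()].
#' @param triggers A [trigger_set()], default [negex_triggers()].
#' @return `annotations` with the `negated` column updated.
#' @examples
#' lex <- tibble::tibble(surface = "myocardial infarction", concept_id = "C_MI")
#' ann <- match_terms("patient denies myocardial infarction", lex)
#' detect_negation("patient denies myocardial infarction", ann)
#' @export
detect_negation <- function(text, annotations, triggers = negex_triggers()) {
  stopifnot(is.character(text), length(text) == 1)
  if (nrow(annotations) == 0) return(annotations)
  trig <- if (inherits(triggers, "trigger_set")) build_trigger_indexes(triggers) else triggers
  tk <- tokenize(text)
  # map character offsets back onto token indices (annotation spans are
  # token-aligned by construction)
  ti <- findInterval(annotations$start, tk$start)
  tj <- findInterval(annotations$end - 1L, tk$start)
  annotations$negated <- negation_flags(tolower(tk$token), tk$start, tk$end,
                                        text, ti, tj, trig)
  annotations
}

#' Annotate a corpus of notes
#'
#' Runs term matching and negation detection over every note and collapses the
#' result to one row per `(note, concept)` pair. A concept mentioned both
#' positively and negated within the same note is recorded as positive
#' (positive evidence dominates within a note). Notes with unparseable dates
#' or missing identifiers are skipped with a warning. Processing is a single
#' pass over the notes.
#'
#' @param notes A tibble with columns `patient_id`, `note_id`, `note_date`
#'   (coercible to `Date`) and `text`, e.g. from [read_notes()].
#' @param lexicon A lexicon tibble (see [read_lexicon()]), already normalized
#'   if normalization is wanted (see [normalize_lexicon()]).
#' @param triggers A [trigger_set()]; default the shipped NegEx rules.
#' @param across_lines Allow multi-token matches across newlines (default
#'   `FALSE`).
#' @return A tibble with columns `note_id`, `patient_id`, `note_date`,
#'   `concept_id`, `negated`, one row per distinct concept per note.
#' @export
annotate_notes <- function(notes, lexicon, triggers = negex_triggers(),
                           across_lines = FALSE) {
  notes <- as_tibble(notes)
  need <- c("patient_id", "note_id", "note_date", "text")
  missing_cols <- setdiff(need, names(notes))
  if (length(missing_cols)) {
    abort(paste0("notes input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(notes) == 0) {
    return(tibble(note_id = character(), patient_id = character(),
                  note_date = as.Date(character()), concept_id = character(),
                  negated = logical()))
  }
  if (nrow(lexicon) == 0) abort("lexicon is empty")
  notes$note_date <- as_date_strict(notes$note_date, "note_date")
  bad <- is.na(notes$note_date) | is.na(notes$patient_id) | is.na(notes$note_id)
  if (any(bad)) {
    warn(sprintf("skipped %d note record(s) with missing id or unparseable date",
                 sum(bad)))
    notes <- notes[!bad, , drop = FALSE]
  }
  texts <- ifelse(is.na(notes$text), "", notes$text)
  idx <- term_index(lexicon$surface, lexicon$concept_id)
  trig <- build_trigger_indexes(triggers)
  tok_all <- gregexpr("[[:alnum:]]+", texts)
  out_row <- vector("list", nrow(notes))
  out_cid <- vector("list", nrow(notes))
  out_neg <- vector("list", nrow(notes))
  for (r in seq_len(nrow(notes))) {
    mm <- tok_all[[r]]
    if (mm[1] == -1) next
    starts <- as.integer(mm) - 1L
    ends <- starts + attr(mm, "match.length")
    toks <- tolower(substring(texts[r], starts + 1L, ends))
    ann <- match_tokens(toks, starts, ends, texts[r], idx, across_lines)
    if (length(ann$concept_id) == 0L) next
    neg <- negation_flags(toks, starts, ends, texts[r], ann$ti, ann$tj, trig)
    # per-note collapse: positive dominates negated
    cid <- ann$concept_id
    pos <- unique(cid[!neg])
    negd <- setdiff(unique(cid[neg]), pos)
    k <- length(pos) + length(negd)
    out_row[[r]] <- rep.int(r, k)
    out_cid[[r]] <- c(pos, negd)
    out_neg[[r]] <- rep(c(FALSE, TRUE), c(length(pos), length(negd)))
  }
  rows <- unlist(out_row, use.names = FALSE)
  if (is.null(rows)) {
    return(tibble(note_id = character(), patient_id = character(),
                  note_date = as.Date(character()), concept_id = character(),
                  negated = logical()))
  }
  tibble(
    note_id = as.character(notes$note_id[rows]),
    patient_id = as.character(notes$patient_id[rows]),
    note_date = notes$note_date[rows],
    concept_id = unlist(out_cid, use.names = FALSE),
    negated = unlist(out_neg, use.names = FALSE)
  ) %>%
    arrange(.data$patient_id, .data$note_date, .data$note_id, .data$concept_id)
}
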