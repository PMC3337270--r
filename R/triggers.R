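#' Read a NegEx trigger file
#'
#' Trigger phrases drive negation detection: a concept mention is flagged
#' negated when a pre-negation phrase precedes it (or a post-negation phrase
#' follows it) within a limited token window, unless a scope terminator or a
#' sentence boundary intervenes. Pseudo-negation phrases contain trigger words
#' but never negate ("no increase").
#'
#' The file format is one phrase per line with section headers `[PRE]`,
#' `[POST]`, `[PSEUDO]`, `[TERM]`; `#` starts a comment.
#'
#' @param path Path to a trigger file. Defaults to the rule set shipped with
#'   the package, drawn from the published NegEx algorithm.
#' @param scope_window Maximum number of tokens between a trigger and the
#'   mention it negates (default 5).
#' @return An object of class `trigger_set`: a list with character vectors
#'   `pre`, `post`, `pseudo`, `term` and the integer `scope_window`.
#' @export
read_triggers <- function(path = NULL, scope_window = 5) {
  if (is.null(path)) {
    path <- system.file("extdata", "negex_triggers.txt", package = "adesignal")
  }
  if (!file.exists(path)) abort(sprintf("trigger file not found: %s", path))
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NULL
  out <- list(pre = character(), post = character(),
              pseudo = character(), term = character())
  keys <- c("[PRE]" = "pre", "[POST]" = "post",
            "[PSEUDO]" = "pseudo", "[TERM]" = "term")
  for (ln in lines) {
    if (ln %in% names(keys)) {
      section <- keys[[ln]]
    } else if (!is.null(section)) {
      out[[section]] <- c(out[[section]], ln)
    }
  }
  trigger_set(pre = out$pre, post = out$post, pseudo = out$pseudo,
              term = out$term, scope_window = scope_window)
}

#' Construct a trigger set
#'
#' @param pre,post,pseudo,term Character vectors of trigger phrases (see
#'   [read_triggers()]). The four lists must be pairwise disjoint.
#' @param scope_window Maximum token gap between trigger and mention
#'   (must be >= 1).
#' @return A `trigger_set` object.
#' @export
trigger_set <- function(pre = character(), post = character(),
                        pseudo = character(), term = character(),
                        scope_window = 5) {
  stopifnot(scope_window >= 1)
  all_phr <- c(pre, post, pseudo, term)
  if (anyDuplicated(tolower(all_phr))) {
    abort("trigger phrase lists must be disjoint")
  }
  structure(
    list(pre = pre, post = post, pseudo = pseudo, term = term,
         scope_window = as.integer(scope_window)),
    class = "trigger_set"
  )
}

#' Default NegEx trigger set
#'
#' Convenience wrapper around [read_triggers()] with the shipped rule file.
#'
#' @param scope_window Token window, passed to [read_triggers()].
#' @return A `trigger_set` object.
#' @export
negex_triggers <- function(scope_window = 5) {
  read_triggers(NULL, scope_window = scope_window)
}

#' @export
print.trigger_set <- function(x, ...) {
  cat(sprintf(
    "<trigger_set> %d pre, %d post, %d pseudo, %d termination; window %d tokens\n",
    length(x$pre), length(x$post), length(x$pseudo), length(x$term),
    x$scope_window))
  invisible(x)
}
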