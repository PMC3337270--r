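# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

as_date_strict <- function(x, what = "date") {
  out <- suppressWarnings(as.Date(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    warn(sprintf("%d %s value(s) could not be parsed and were set to NA", sum(bad), what))
  }
  out
}

# Split a phrase into lowercase alphanumeric tokens.
phrase_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^[:alnum:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

phrase_key <- function(x) {
  vapply(phrase_tokens(x), paste, character(1), collapse = " ")
}
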