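# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (seed, parameters).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    mb_bad_argument("`seed` must be a single number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Validate that a regular expression compiles in the PCRE dialect used
# throughout the text wrapper; returns TRUE or the compile error message.
regex_check <- function(pattern) {
  out <- tryCatch({
    grepl(pattern, "", perl = TRUE)
    TRUE
  }, error = function(e) conditionMessage(e), warning = function(w) conditionMessage(w))
  out
}

# First match of `pattern` in text restricted to [from, to] (1-based,
# inclusive); returns c(start, end) absolute offsets or NULL.
regex_find <- function(pattern, text, from, to) {
  if (from > to) return(NULL)
  window <- substr(text, from, to)
  m <- regexpr(pattern, window, perl = TRUE)
  if (m[1] == -1L) return(NULL)
  start <- from + as.integer(m[1]) - 1L
  c(start = start, end = start + attr(m, "match.length") - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))
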