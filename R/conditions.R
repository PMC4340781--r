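#' @keywords internal
"_PACKAGE"

# Structured condition helpers. Every user-facing failure in the package is a
# classed condition so callers (and tests) can dispatch on the kind of error
# rather than on message text.

mb_abort <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "metabind_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

mb_conflict      <- function(msg, ...) mb_abort("mb_conflict_error", msg, ...)
mb_not_found     <- function(msg, ...) mb_abort("mb_not_found_error", msg, ...)
mb_invalid       <- function(msg, ...) mb_abort("mb_validation_error", msg, ...)
mb_bad_argument  <- function(msg, ...) mb_abort("mb_argument_error", msg, ...)
mb_parse_failure <- function(msg, ...) mb_abort("mb_parse_error", msg, ...)
mb_bad_path      <- function(msg, ...) mb_abort("mb_path_error", msg, ...)
mb_unsupported   <- function(msg, ...) mb_abort("mb_unsupported_error", msg, ...)
mb_schema_fail   <- function(msg, ...) mb_abort("mb_schema_error", msg, ...)
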