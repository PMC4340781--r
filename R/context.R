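# Execution context: the typed name -> value store from which call
# parameters are bound during operation execution, plus the append-only
# execution trace.

#' Initialize an execution context
#'
#' @param parameters Named list of initial values (request parameters).
#' @param types Optional named character vector of semantic types for the
#'   parameters; unnamed parameters default to `"string"` for character
#'   scalars and `"any"` otherwise.
#' @return An environment of class `mb_context`.
#' @export
init_context <- function(parameters = list(), types = NULL) {
  parameters <- as.list(parameters)
  nms <- names(parameters)
  if (length(parameters) && (is.null(nms) || any(!nzchar(nms)))) {
    mb_bad_argument("all context parameters must be named")
  }
  if (anyDuplicated(nms)) {
    mb_bad_argument(sprintf("duplicate parameter name(s): %s",
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  ctx <- new.env(parent = emptyenv())
  ctx$values <- list()
  ctx$trace <- list()
  class(ctx) <- "mb_context"
  for (nm in nms) {
    tp <- if (!is.null(types) && nm %in% names(types)) types[[nm]]
          else if (is_string(parameters[[nm]])) "string" else "any"
    context_put(ctx, nm, parameters[[nm]], tp)
  }
  ctx
}

#' Store a typed value in a context
#'
#' @param context An `mb_context`.
#' @param name Entry name.
#' @param value Value.
#' @param type Semantic type string.
#' @return The context, invisibly.
#' @export
context_put <- function(context, name, value, type = "any") {
  stopifnot(inherits(context, "mb_context"))
  if (!is_string(name) || !nzchar(name)) mb_bad_argument("context names must be non-empty strings")
  context$values[[name]] <- list(type = type, value = value)
  invisible(context)
}

#' @rdname context_put
#' @export
context_get <- function(context, name) {
  v <- context$values[[name]]
  if (is.null(v)) mb_not_found(sprintf("no context value named '%s'", name))
  v$value
}

#' @rdname context_put
#' @export
context_has <- function(context, name) !is.null(context$values[[name]])

#' @rdname context_put
#' @export
context_type <- function(context, name) {
  v <- context$values[[name]]
  if (is.null(v)) mb_not_found(sprintf("no context value named '%s'", name))
  v$type
}

#' @rdname context_put
#' @export
context_names <- function(context) names(context$values)

trace_append <- function(context, state, event, guard, action, outcome) {
  context$trace[[length(context$trace) + 1L]] <-
    list(state = state, event = event, guard = guard, action = action,
         outcome = outcome)
  invisible(context)
}

#' Read the execution trace of a context
#'
#' @param context An `mb_context`.
#' @return A data.frame with one row per fired transition: `state`, `event`,
#'   `guard`, `action`, `outcome`.
#' @export
context_trace <- function(context) {
  stopifnot(inherits(context, "mb_context"))
  if (!length(context$trace)) {
    return(data.frame(state = character(), event = character(),
                      guard = logical(), action = character(),
                      outcome = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(context$trace, function(e) {
    data.frame(state = e$state, event = e$event, guard = e$guard,
               action = e$action, outcome = e$outcome,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a context to JSON
#'
#' Only serializable values survive a round trip; live objects (functions,
#' environments) are represented by a reference marker.
#'
#' @param context An `mb_context`.
#' @return JSON text.
#' @export
context_to_json <- function(context) {
  vals <- lapply(context$values, function(v) {
    if (is.function(v$value) || is.environment(v$value)) {
      list(type = v$type, value = NULL, live = TRUE)
    } else {
      list(type = v$type, value = v$value, live = FALSE)
    }
  })
  as.character(jsonlite::toJSON(list(values = vals, trace = context$trace),
                                auto_unbox = TRUE, null = "null", digits = NA))
}

#' Restore a context from JSON
#'
#' @param json JSON text from [context_to_json()].
#' @return An `mb_context` (live values are dropped).
#' @export
context_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ctx <- init_context()
  for (nm in names(doc$values)) {
    v <- doc$values[[nm]]
    if (isTRUE(v$live)) next
    context_put(ctx, nm, v$value, v$type)
  }
  ctx$trace <- doc$trace
  ctx
}
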