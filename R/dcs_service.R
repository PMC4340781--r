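# Client-facing service façade: routes biologist operations either to a
# single generic call (simple operations) or to a state-machine execution
# (complex operations). The core is in-process; an optional JSON-over-HTTP
# endpoint exposes the same three calls.

#' Bundle a registry and runtime state into a service
#'
#' @param registry Ontology registry ([new_registry()]).
#' @param components Component registry of live targets
#'   ([new_component_registry()]).
#' @param recipes,widenings Parameter-construction recipes and type
#'   widenings (see [bind_parameters()]).
#' @return An object of class `mb_dcs`.
#' @export
dcs_service <- function(registry = new_registry(),
                        components = new_component_registry(),
                        recipes = list(), widenings = list()) {
  svc <- new.env(parent = emptyenv())
  svc$registry <- registry
  svc$components <- components
  svc$recipes <- recipes
  svc$widenings <- widenings
  class(svc) <- "mb_dcs"
  svc
}

#' Describe an operation request
#'
#' @param operation_name,source_name,element_name The operation triple, e.g.
#'   `("FetchData", "EBI", "Protein")`.
#' @param parameters Named list of parameter values.
#' @return An object of class `mb_request`.
#' @export
operation_request <- function(operation_name, source_name, element_name,
                              parameters = list()) {
  for (f in c(operation_name, source_name, element_name)) {
    if (!is_string(f) || !nzchar(f)) {
      mb_bad_argument("operation, source and element names must be non-empty strings")
    }
  }
  structure(list(operation_name = operation_name, source_name = source_name,
                 element_name = element_name, parameters = as.list(parameters)),
            class = "mb_request")
}

#' Execute a biologist-level operation
#'
#' Initializes a fresh execution context from the request parameters, routes
#' the operation through the ontology (simple -> one [translate_and_call()];
#' complex -> load and run the referenced state machine), and wraps the
#' result with the element's display hint. Simple operations never load a
#' state machine, so their trace stays empty.
#'
#' @param service An [dcs_service()].
#' @param request An [operation_request()] (or the operation name, with the
#'   remaining fields passed positionally).
#' @param source_name,element_name,parameters Used when `request` is given
#'   as an operation name.
#' @return An object of class `mb_result`: `status`, `payload`,
#'   `payload_type`, `display_hint`, `trace`.
#' @export
ds_operation <- function(service, request, source_name = NULL,
                         element_name = NULL, parameters = list()) {
  stopifnot(inherits(service, "mb_dcs"))
  if (!inherits(request, "mb_request")) {
    request <- operation_request(request, source_name, element_name, parameters)
  }
  reg <- service$registry
  src <- reg$sources[[request$source_name]]
  if (is.null(src)) {
    mb_not_found(sprintf("source '%s' is not registered", request$source_name))
  }
  el <- src$elements[[request$element_name]]
  if (is.null(el) && request$element_name != "*") {
    mb_not_found(sprintf("element '%s' is not classified for source '%s'",
                         request$element_name, request$source_name))
  }
  route <- lookup_state_machine_model(reg, request$operation_name,
                                      request$source_name, request$element_name)

  # semantic types for parameters that match classified attribute names
  types <- NULL
  if (!is.null(el) && length(el$attributes)) {
    at <- stats::setNames(vapply(el$attributes, `[[`, "", "type"),
                          vapply(el$attributes, `[[`, "", "name"))
    types <- at[names(at) %in% names(request$parameters)]
  }
  ctx <- init_context(request$parameters, types = types)

  if (route$kind == "simple") {
    out <- translate_and_call(reg, route$target, request$source_name, ctx,
                              service$components, recipes = service$recipes,
                              widenings = service$widenings)
    mapping <- resolve_mapping(reg, route$target, request$source_name)
    payload <- out$result
    payload_type <- mapping$result_type
  } else {
    model <- load_model(get_model_text(reg, route$target))
    binder <- make_registry_binder(reg, request$source_name,
                                   service$components,
                                   recipes = service$recipes,
                                   widenings = service$widenings)
    execute_model(model, ctx, binder)
    tr <- context_trace(ctx)
    acts <- tr$action[!is.na(tr$action) & tr$outcome == "ok"]
    last_op <- acts[length(acts)]
    mapping <- resolve_mapping(reg, last_op, request$source_name)
    payload <- context_get(ctx, mapping$result_key)
    payload_type <- mapping$result_type
  }
  structure(list(status = "ok", payload = payload, payload_type = payload_type,
                 display_hint = if (!is.null(el)) el$ui_hint,
                 trace = context_trace(ctx)),
            class = "mb_result")
}

#' @export
print.mb_result <- function(x, ...) {
  cat(sprintf("<operation result: %s, payload type '%s'>\n", x$status, x$payload_type))
  if (is.character(x$payload)) {
    cat(substr(paste(x$payload, collapse = "\n"), 1, 200), "\n")
  }
  if (nrow(x$trace)) {
    cat("trace:\n")
    print(x$trace)
  }
  invisible(x)
}

result_to_json <- function(res) {
  as.character(jsonlite::toJSON(list(
    status = res$status,
    payload = if (is.function(res$payload) || is.environment(res$payload)) NULL
              else res$payload,
    payload_type = res$payload_type,
    display_hint = res$display_hint,
    trace = if (nrow(res$trace)) res$trace else NULL
  ), auto_unbox = TRUE, null = "null", digits = NA))
}

#' HTTP handler exposing a service
#'
#' Routes `GET /ds_list`, `GET /ds_metadata?source=NAME`, and
#' `POST /ds_operation` (JSON body with `operation_name`, `source_name`,
#' `element_name`, `parameters`) to the in-process implementations; the two
#' façades return identical serialized answers.
#'
#' @param service An [dcs_service()].
#' @return A handler function for [serve_http_blocking()].
#' @export
dcs_http_handler <- function(service) {
  force(service)
  function(req) {
    path <- sub("\\?.*$", "", req$path)
    if (req$method == "GET" && path == "/ds_list") {
      return(list(status = 200L, body = as.character(
        jsonlite::toJSON(get_ds_list(service$registry), digits = NA))))
    }
    if (req$method == "GET" && path == "/ds_metadata") {
      q <- sub("^.*\\?", "", req$path)
      src <- sub("^source=", "", q)
      src <- utils::URLdecode(src)
      md <- tryCatch(get_ds_metadata(service$registry, src),
                     mb_not_found_error = function(e) e)
      if (inherits(md, "condition")) {
        return(list(status = 404L, body = as.character(jsonlite::toJSON(
          list(error = conditionMessage(md)), auto_unbox = TRUE))))
      }
      return(list(status = 200L, body = as.character(
        jsonlite::toJSON(md, auto_unbox = TRUE, null = "null", digits = NA))))
    }
    if (req$method == "POST" && path == "/ds_operation") {
      parsed <- tryCatch(
        jsonlite::fromJSON(rawToChar(req$body), simplifyVector = FALSE),
        error = function(e) e)
      if (inherits(parsed, "condition") || is.null(parsed$operation_name)) {
        return(list(status = 400L, body = as.character(jsonlite::toJSON(
          list(error = "malformed JSON request body"), auto_unbox = TRUE))))
      }
      res <- tryCatch(
        ds_operation(service,
                     operation_request(parsed$operation_name,
                                       parsed$source_name,
                                       parsed$element_name,
                                       parsed$parameters %||% list())),
        error = function(e) e)
      if (inherits(res, "condition")) {
        status <- if (inherits(res, "mb_not_found_error")) 404L else 500L
        return(list(status = status, body = as.character(jsonlite::toJSON(
          list(status = "error", error = conditionMessage(res)),
          auto_unbox = TRUE))))
      }
      return(list(status = 200L, body = result_to_json(res)))
    }
    list(status = 404L, body = as.character(jsonlite::toJSON(
      list(error = sprintf("no route %s %s", req$method, path)),
      auto_unbox = TRUE)))
  }
}

#' Serve a service over HTTP in a child process
#'
#' @param setup_code R code (string) evaluated in the child; must produce a
#'   service object named `service` (e.g.
#'   `"service <- make_mock_sources(seed = 1)$service"`).
#' @param port Port to listen on (see [free_port()]).
#' @param max_requests Child exits after serving this many requests.
#' @return A server handle (see [start_server_process()]).
#' @export
serve_dcs <- function(setup_code, port, max_requests = 1000L) {
  code <- paste0(
    setup_code, "\n",
    sprintf("serve_http_blocking(dcs_http_handler(service), %d, max_requests = %d)",
            port, max_requests))
  start_server_process(code, port)
}
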