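# Generic web page wrapper: a declarative model of a form-submission web API
# (URL, method, headers, form parts, response filters), request construction
# with deterministic multipart boundaries, lenient HTML response parsing, and
# value extraction by indexed tag paths.
#
# Tag-path ordinals count the node's position among ALL element siblings of
# its parent, 0-based (so BODY[3] is the fourth element child of HTML). A
# per-tag ordinal mode (TD[1] = the second TD) is available via
# `ordinal_mode = "per-tag"`.

#' Parse a tag path
#'
#' @param x A path string such as
#'   `"HTML[0]/BODY[3]/DIV[1]/DIV[3]/DIV[7]/TABLE[7]/TR[1]/TD[1]"`. Tag names
#'   are uppercase-normalized; ordinals are non-negative integers.
#' @return An object of class `mb_tag_path`.
#' @export
tag_path <- function(x) {
  if (inherits(x, "mb_tag_path")) return(x)
  if (!is_string(x) || !nzchar(x)) mb_bad_path("tag path must be a non-empty string")
  steps <- strsplit(x, "/", fixed = TRUE)[[1]]
  parsed <- lapply(steps, function(s) {
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)\\[([0-9]+)\\]$", s))[[1]]
    if (length(m) != 3L) mb_bad_path(sprintf("malformed tag-path step '%s'", s))
    list(tag = toupper(m[2]), ordinal = as.integer(m[3]))
  })
  structure(list(steps = parsed, text = paste(vapply(parsed, function(p) {
    sprintf("%s[%d]", p$tag, p$ordinal)
  }, ""), collapse = "/")), class = "mb_tag_path")
}

#' @export
format.mb_tag_path <- function(x, ...) x$text

#' @export
print.mb_tag_path <- function(x, ...) {
  cat("<tag path>", x$text, "\n")
  invisible(x)
}

#' Describe a web-page API
#'
#' @param url Endpoint URL (an absolute URL or a path for use with a
#'   supplied transport).
#' @param http_method `"GET"` or `"POST"`.
#' @param request_headers Named list of default header values (e.g.
#'   `Accept`, `Host`).
#' @param user_params Ordered character vector of form-part names supplied at
#'   call time (e.g. `QUERY`, `JOB_TITLE`, `DATABASE`).
#' @param default_params Named list of fixed form parts (e.g. `QUERYFILE`,
#'   `db`, `BLAST_PROGRAMS`).
#' @param encoding `"multipart-form"` or `"urlencoded"`.
#' @param boundary_seed Integer seed for the multipart boundary generator;
#'   fixing it makes request bodies byte-reproducible.
#' @param filters Named list of response filters ([tag_path()] or path
#'   strings); names are the keys of the extracted-value map.
#' @param ordinal_mode `"element"` (ordinal among all element siblings,
#'   the default) or `"per-tag"` (ordinal among same-tag siblings).
#' @return An object of class `mb_web_model`.
#' @export
web_api_model <- function(url, http_method = c("POST", "GET"),
                          request_headers = list(),
                          user_params = character(),
                          default_params = list(),
                          encoding = c("multipart-form", "urlencoded"),
                          boundary_seed = NULL,
                          filters = list(),
                          ordinal_mode = c("element", "per-tag")) {
  http_method <- match.arg(http_method)
  encoding <- match.arg(encoding)
  ordinal_mode <- match.arg(ordinal_mode)
  user_params <- as.character(user_params)
  both <- intersect(user_params, names(default_params))
  if (length(both)) {
    mb_invalid(sprintf("parameter(s) both user and default: %s",
                       paste(both, collapse = ", ")))
  }
  if (length(filters)) {
    if (is.null(names(filters)) || any(!nzchar(names(filters))) ||
        anyDuplicated(names(filters))) {
      mb_invalid("filters must have unique non-empty names")
    }
    filters <- lapply(filters, tag_path)
  }
  structure(list(url = url, http_method = http_method,
                 request_headers = request_headers,
                 user_params = user_params,
                 default_params = default_params,
                 encoding = encoding, boundary_seed = boundary_seed,
                 filters = filters, ordinal_mode = ordinal_mode),
            class = "mb_web_model")
}

make_boundary <- function(seed) {
  token <- if (is.null(seed)) {
    paste(sample(c(letters, LETTERS, 0:9), 24, replace = TRUE), collapse = "")
  } else {
    with_seed(seed, paste(sample(c(letters, LETTERS, 0:9), 24, replace = TRUE),
                          collapse = ""))
  }
  paste0("----metabind", token)
}

url_encode <- function(x) utils::URLencode(as.character(x), reserved = TRUE)

#' Construct an HTTP request from a web-API model
#'
#' The body carries every user parameter (in declared order) followed by
#' every default parameter, each exactly once. Multipart bodies use a
#' boundary from a seeded generator, used consistently in the Content-Type
#' header and the body.
#'
#' @param model An [web_api_model()].
#' @param values Named list/character vector covering every user parameter.
#' @return A list of class `mb_http_request` with fields `method`, `url`,
#'   `headers`, `body` (raw vector), `content_type`.
#' @export
build_request <- function(model, values = list()) {
  stopifnot(inherits(model, "mb_web_model"))
  values <- as.list(values)
  missing <- setdiff(model$user_params, names(values))
  if (length(missing)) {
    mb_bad_argument(sprintf("missing user parameter(s): %s",
                            paste(missing, collapse = ", ")),
                    params = missing)
  }
  extra <- setdiff(names(values), model$user_params)
  if (length(extra)) {
    mb_bad_argument(sprintf("unknown parameter(s): %s", paste(extra, collapse = ", ")),
                    params = extra)
  }
  parts <- c(stats::setNames(lapply(model$user_params, function(p) values[[p]]),
                             model$user_params),
             model$default_params)
  headers <- model$request_headers
  if (!length(parts)) {
    return(structure(list(method = model$http_method, url = model$url,
                          headers = headers, body = raw(0), content_type = NULL),
                     class = "mb_http_request"))
  }
  if (model$encoding == "multipart-form") {
    boundary <- make_boundary(model$boundary_seed)
    chunks <- vapply(names(parts), function(nm) {
      paste0("--", boundary, "\r\n",
             "Content-Disposition: form-data; name=\"", nm, "\"\r\n\r\n",
             as.character(parts[[nm]]), "\r\n")
    }, "")
    body_txt <- paste0(paste0(chunks, collapse = ""), "--", boundary, "--\r\n")
    content_type <- paste0("multipart/form-data; boundary=", boundary)
  } else {
    body_txt <- paste(vapply(names(parts), function(nm) {
      paste0(url_encode(nm), "=", url_encode(parts[[nm]]))
    }, ""), collapse = "&")
    content_type <- "application/x-www-form-urlencoded"
  }
  body <- charToRaw(enc2utf8(body_txt))
  headers[["Content-Type"]] <- content_type
  headers[["Content-Length"]] <- as.character(length(body))
  structure(list(method = model$http_method, url = model$url, headers = headers,
                 body = body, content_type = content_type),
            class = "mb_http_request")
}

#' Parse an HTML response into a tag-path-addressable structure
#'
#' Uses a lenient (libxml2) HTML parse; catastrophically malformed input
#' yields a best-effort tree. Parsing is deterministic.
#'
#' @param html_text HTML text.
#' @return An object of class `mb_tagdoc`.
#' @export
parse_response_tags <- function(html_text) {
  if (!is_string(html_text) || !nzchar(html_text)) {
    mb_bad_argument("html_text must be a non-empty string")
  }
  doc <- xml2::read_html(html_text)
  structure(list(doc = doc, root = xml2::xml_root(doc)), class = "mb_tagdoc")
}

#' Resolve a tag path against a parsed page
#'
#' @param parsed An `mb_tagdoc` from [parse_response_tags()].
#' @param path A [tag_path()] or path string.
#' @param ordinal_mode `"element"` or `"per-tag"` (see [web_api_model()]).
#' @return The trimmed text content of the addressed node.
#' @export
apply_filter <- function(parsed, path, ordinal_mode = c("element", "per-tag")) {
  stopifnot(inherits(parsed, "mb_tagdoc"))
  ordinal_mode <- match.arg(ordinal_mode)
  path <- tag_path(path)
  steps <- path$steps
  miss <- function(i, why) {
    mb_abort("mb_extraction_miss",
             sprintf("tag path miss at step %d (%s[%d]): %s",
                     i, steps[[i]]$tag, steps[[i]]$ordinal, why),
             step = i, path = path$text)
  }
  root <- parsed$root
  s1 <- steps[[1]]
  if (!identical(toupper(xml2::xml_name(root)), s1$tag)) miss(1L, "root tag differs")
  if (s1$ordinal != 0L) miss(1L, "document has a single root element")
  node <- root
  if (length(steps) > 1L) {
    for (i in 2:length(steps)) {
      st <- steps[[i]]
      kids <- xml2::xml_children(node)   # element children only
      if (ordinal_mode == "per-tag") {
        kids <- kids[toupper(xml2::xml_name(kids)) == st$tag]
      }
      if (st$ordinal + 1L > length(kids)) miss(i, "ordinal out of range")
      cand <- kids[[st$ordinal + 1L]]
      if (!identical(toupper(xml2::xml_name(cand)), st$tag)) {
        miss(i, sprintf("element at ordinal %d is <%s>", st$ordinal,
                        xml2::xml_name(cand)))
      }
      node <- cand
    }
  }
  trimws(xml2::xml_text(node))
}

#' Compute the tag path of every element holding a target string
#'
#' A helper replacing an interactive page-sampling tool: given a page and a
#' target value, returns the tag path(s) of the elements whose trimmed text
#' equals the target.
#'
#' @param html_text HTML text.
#' @param target Target string.
#' @param ordinal_mode `"element"` or `"per-tag"`.
#' @return Character vector of tag-path strings.
#' @export
find_tag_paths <- function(html_text, target, ordinal_mode = c("element", "per-tag")) {
  ordinal_mode <- match.arg(ordinal_mode)
  parsed <- parse_response_tags(html_text)
  hits <- character()
  walk <- function(node, prefix) {
    if (identical(trimws(xml2::xml_text(node)), target)) {
      hits <<- c(hits, prefix)
    }
    kids <- xml2::xml_children(node)
    for (i in seq_along(kids)) {
      k <- kids[[i]]
      ord <- if (ordinal_mode == "element") i - 1L else {
        sum(toupper(xml2::xml_name(kids[seq_len(i)])) == toupper(xml2::xml_name(k))) - 1L
      }
      walk(k, paste0(prefix, "/", toupper(xml2::xml_name(k)), "[", ord, "]"))
    }
  }
  root <- parsed$root
  walk(root, paste0(toupper(xml2::xml_name(root)), "[0]"))
  hits
}

#' Invoke a web source end to end
#'
#' Builds the request, sends it through `transport`, parses the response and
#' applies every configured filter. Filter misses do not abort the call:
#' other filters' results are still reported.
#'
#' @param model An [web_api_model()] with at least one filter.
#' @param values Named values covering the model's user parameters.
#' @param transport A function taking the `mb_http_request` and returning the
#'   response as a list with a `body` field (or a plain HTML string). See
#'   [http_transport()] for a socket transport to a local server.
#' @return A list with `values` (filter-name -> extracted text) and `misses`
#'   (filter-name -> miss message).
#' @export
invoke_web_source <- function(model, values, transport) {
  stopifnot(inherits(model, "mb_web_model"), is.function(transport))
  req <- build_request(model, values)
  resp <- tryCatch(transport(req), error = function(e) {
    mb_abort("mb_transport_error",
             paste("transport failure:", conditionMessage(e)))
  })
  body <- if (is.list(resp)) resp$body else resp
  if (is.raw(body)) body <- rawToChar(body)
  parsed <- tryCatch(parse_response_tags(body), error = function(e) NULL)
  out <- list()
  misses <- list()
  for (nm in names(model$filters)) {
    if (is.null(parsed)) {
      misses[[nm]] <- "empty or unparseable response"
      next
    }
    val <- tryCatch(apply_filter(parsed, model$filters[[nm]], model$ordinal_mode),
                    mb_extraction_miss = function(e) e)
    if (inherits(val, "condition")) misses[[nm]] <- conditionMessage(val)
    else out[[nm]] <- val
  }
  list(values = out, misses = misses)
}

# ---- configuration file dialect --------------------------------------------

#' Serialize a web-API model to its XML configuration dialect
#'
#' @param model An [web_api_model()].
#' @param file Optional path to write to.
#' @return XML text.
#' @export
web_model_to_xml <- function(model, file = NULL) {
  stopifnot(inherits(model, "mb_web_model"))
  doc <- xml2::xml_new_root("webPageAPI", url = model$url,
                            method = model$http_method,
                            encoding = model$encoding,
                            ordinalMode = model$ordinal_mode)
  if (!is.null(model$boundary_seed)) {
    xml2::xml_set_attr(doc, "boundarySeed", as.character(model$boundary_seed))
  }
  for (nm in names(model$request_headers)) {
    h <- xml2::xml_add_child(doc, "header", name = nm)
    xml2::xml_set_text(h, as.character(model$request_headers[[nm]]))
  }
  for (p in model$user_params) {
    xml2::xml_add_child(doc, "param", name = p, kind = "user")
  }
  for (nm in names(model$default_params)) {
    p <- xml2::xml_add_child(doc, "param", name = nm, kind = "default")
    xml2::xml_set_text(p, as.character(model$default_params[[nm]]))
  }
  for (nm in names(model$filters)) {
    f <- xml2::xml_add_child(doc, "filter", name = nm)
    xml2::xml_set_text(f, model$filters[[nm]]$text)
  }
  txt <- as.character(doc)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Load a web-API model from its XML configuration dialect
#'
#' @param x XML text or file path.
#' @return An `mb_web_model`.
#' @export
web_model_from_xml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "webPageAPI") mb_parse_failure("not a webPageAPI document")
  headers <- list()
  for (h in xml2::xml_find_all(doc, "./header")) {
    headers[[xml2::xml_attr(h, "name")]] <- xml2::xml_text(h)
  }
  user_params <- xml2::xml_attr(xml2::xml_find_all(doc, "./param[@kind='user']"), "name")
  defaults <- list()
  for (p in xml2::xml_find_all(doc, "./param[@kind='default']")) {
    defaults[[xml2::xml_attr(p, "name")]] <- xml2::xml_text(p)
  }
  filters <- list()
  for (f in xml2::xml_find_all(doc, "./filter")) {
    filters[[xml2::xml_attr(f, "name")]] <- xml2::xml_text(f)
  }
  seed <- xml2::xml_attr(doc, "boundarySeed")
  web_api_model(url = xml2::xml_attr(doc, "url"),
                http_method = xml2::xml_attr(doc, "method"),
                request_headers = headers,
                user_params = as.character(user_params),
                default_params = defaults,
                encoding = xml2::xml_attr(doc, "encoding"),
                boundary_seed = if (is.na(seed)) NULL else as.integer(seed),
                filters = filters,
                ordinal_mode = xml2::xml_attr(doc, "ordinalMode"))
}
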