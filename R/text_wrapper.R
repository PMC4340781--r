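# Generic text wrapper: schema-driven parsing of structured biological flat
# files (GenBank record style) into a document tree.
#
# A text schema is a hierarchy of nodes, each delimited by regular-expression
# start/end patterns. Delimiter text belongs to neither adjacent node: a
# node's content begins after its start match and ends before its end match
# (or before the next sibling's start). Siblings claim spans left-to-right by
# earliest start-pattern match.

STRIP_RULES <- c("none", "trim", "squish", "origin_sequence")

validate_text_node <- function(node, path = node$node_name %||% "?") {
  if (!is_string(node$node_name) || !nzchar(node$node_name)) {
    mb_schema_fail(sprintf("node under '%s' lacks a name", path))
  }
  for (field in c("start_pattern", "end_pattern")) {
    p <- node[[field]]
    if (!is.null(p)) {
      ok <- regex_check(p)
      if (!isTRUE(ok)) {
        mb_schema_fail(sprintf("invalid %s on node '%s': %s", field, path, ok))
      }
    }
  }
  if (isTRUE(node$repeatable) && is.null(node$start_pattern)) {
    mb_schema_fail(sprintf("repeatable node '%s' must declare a start_pattern", path))
  }
  if (!is.null(node$strip_rule) && !node$strip_rule %in% STRIP_RULES) {
    mb_schema_fail(sprintf("unknown strip_rule '%s' on node '%s'", node$strip_rule, path))
  }
  starts <- vapply(node$children, function(ch) ch$start_pattern %||% NA_character_, "")
  dup <- starts[!is.na(starts)][duplicated(starts[!is.na(starts)])]
  if (length(dup)) {
    mb_schema_fail(sprintf("ambiguous sibling start patterns under '%s': %s",
                           path, paste(unique(dup), collapse = ", ")))
  }
  for (ch in node$children) validate_text_node(ch, paste0(path, "/", ch$node_name))
  invisible(TRUE)
}

as_text_node <- function(spec) {
  node <- list(node_name = spec$node_name %||% spec$name,
               start_pattern = spec$start_pattern,
               end_pattern = spec$end_pattern,
               repeatable = isTRUE(spec$repeatable),
               strip_rule = spec$strip_rule %||% "none",
               children = lapply(spec$children %||% list(), as_text_node))
  class(node) <- "mb_text_node"
  node
}

#' Compile a declarative text schema
#'
#' Builds a [parse_flat_file()]-ready schema from a declarative nested
#' description. Every pattern is validated against the PCRE dialect; sibling
#' nodes with identical start patterns are rejected as ambiguous.
#'
#' @param spec A list with fields `name`, `root` (nested node description
#'   with `node_name`, optional `start_pattern`/`end_pattern`, `repeatable`,
#'   `strip_rule`, `children`), and optional `tokens` (literal marker
#'   strings).
#' @return An object of class `mb_text_schema`.
#' @export
build_text_schema <- function(spec) {
  if (is.null(spec$root)) mb_schema_fail("schema spec must declare a root node")
  tokens <- as.character(spec$tokens %||% character())
  if (any(!nzchar(tokens)) || anyDuplicated(tokens)) {
    mb_schema_fail("tokens must be non-empty and unique")
  }
  root <- as_text_node(spec$root)
  validate_text_node(root)
  structure(list(name = spec$name %||% "schema", root = root, tokens = tokens),
            class = "mb_text_schema")
}

# ---- schema file dialect (XML) ---------------------------------------------

node_to_xml <- function(node, parent) {
  x <- xml2::xml_add_child(parent, "node", name = node$node_name)
  if (node$repeatable) xml2::xml_set_attr(x, "repeatable", "true")
  if (!identical(node$strip_rule, "none")) xml2::xml_set_attr(x, "strip", node$strip_rule)
  if (!is.null(node$start_pattern)) {
    xml2::xml_set_text(xml2::xml_add_child(x, "start"), node$start_pattern)
  }
  if (!is.null(node$end_pattern)) {
    xml2::xml_set_text(xml2::xml_add_child(x, "end"), node$end_pattern)
  }
  for (ch in node$children) node_to_xml(ch, x)
}

#' Serialize a text schema to its XML file dialect
#'
#' @param schema An `mb_text_schema`.
#' @param file Optional path to write to.
#' @return XML text (invisibly when `file` is given).
#' @export
text_schema_to_xml <- function(schema, file = NULL) {
  stopifnot(inherits(schema, "mb_text_schema"))
  doc <- xml2::xml_new_root("textSchema", name = schema$name)
  if (length(schema$tokens)) {
    tk <- xml2::xml_add_child(doc, "tokens")
    for (t in schema$tokens) xml2::xml_set_text(xml2::xml_add_child(tk, "token"), t)
  }
  node_to_xml(schema$root, doc)
  txt <- as.character(doc)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

node_from_xml <- function(x) {
  getp <- function(tag) {
    n <- xml2::xml_find_first(x, paste0("./", tag))
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  list(node_name = xml2::xml_attr(x, "name"),
       start_pattern = getp("start"),
       end_pattern = getp("end"),
       repeatable = identical(xml2::xml_attr(x, "repeatable"), "true"),
       strip_rule = xml2::xml_attr(x, "strip") %|na|% "none",
       children = lapply(xml2::xml_find_all(x, "./node"), node_from_xml))
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Load a text schema from its XML file dialect
#'
#' @param x XML text or a file path.
#' @return An `mb_text_schema`.
#' @export
text_schema_from_xml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "textSchema") mb_parse_failure("not a textSchema document")
  root_x <- xml2::xml_find_first(doc, "./node")
  if (inherits(root_x, "xml_missing")) mb_parse_failure("textSchema lacks a root node")
  tokens <- xml2::xml_text(xml2::xml_find_all(doc, "./tokens/token"))
  build_text_schema(list(name = xml2::xml_attr(doc, "name"),
                         tokens = tokens, root = node_from_xml(root_x)))
}

# ---- token suggestion ------------------------------------------------------

#' Suggest schema tokens from sample documents
#'
#' Returns the maximal line-initial words that occur at the start of a line
#' in every sample, ordered by first occurrence in the first sample. Advisory
#' input for schema construction ("LOCUS", "FEATURES", "ORIGIN" for GenBank
#' records).
#'
#' @param samples Character vector (or list) of document texts.
#' @return Character vector of token strings.
#' @export
suggest_tokens <- function(samples) {
  samples <- as.character(unlist(samples))
  if (!length(samples)) mb_bad_argument("at least one sample document is required")
  words_of <- function(s) {
    m <- regmatches(s, gregexpr("(?m)^[A-Za-z][A-Za-z_]*", s, perl = TRUE))[[1]]
    unique(m)
  }
  per_sample <- lapply(samples, words_of)
  shared <- Reduce(intersect, per_sample)
  # keep the first sample's order of first occurrence
  per_sample[[1]][per_sample[[1]] %in% shared]
}

# ---- parsing ---------------------------------------------------------------

apply_strip <- function(raw, rule) {
  switch(rule,
         none = raw,
         trim = trimws(raw),
         squish = squish(raw),
         origin_sequence = toupper(gsub("[^A-Za-z]", "", raw)),
         raw)
}

# Earliest start match of the first following sibling that declares a start
# pattern; NULL if none declares one or the pattern does not occur.
next_sibling_start <- function(children, i, text, from, to) {
  if (i >= length(children)) return(NULL)
  for (j in (i + 1L):length(children)) {
    p <- children[[j]]$start_pattern
    if (!is.null(p)) return(regex_find(p, text, from, to))
  }
  NULL
}

parse_node_span <- function(node, text, lo, hi) {
  if (!length(node$children)) {
    raw <- if (lo > hi) "" else substr(text, lo, hi)
    return(doc_node(node$node_name, apply_strip(raw, node$strip_rule),
                    attributes = list(span_start = lo, span_end = hi)))
  }
  kids <- parse_children(node$children, text, lo, hi)
  doc_node(node$node_name, "", attributes = list(span_start = lo, span_end = hi),
           children = kids)
}

parse_children <- function(children, text, lo, hi) {
  out <- list()
  cursor <- lo
  for (i in seq_along(children)) {
    child <- children[[i]]
    if (child$repeatable) {
      repeat {
        m <- regex_find(child$start_pattern, text, cursor, hi)
        if (is.null(m)) break
        content_start <- m[["end"]] + 1L
        limit <- hi + 1L
        nxt <- regex_find(child$start_pattern, text, content_start, hi)
        if (!is.null(nxt)) limit <- min(limit, nxt[["start"]])
        sib <- next_sibling_start(children, i, text, content_start, hi)
        if (!is.null(sib)) limit <- min(limit, sib[["start"]])
        out[[length(out) + 1L]] <- parse_node_span(child, text, content_start, limit - 1L)
        cursor <- limit
      }
    } else {
      if (!is.null(child$start_pattern)) {
        m <- regex_find(child$start_pattern, text, cursor, hi)
        if (is.null(m)) {
          mb_parse_failure(sprintf(
            "start pattern of node '%s' not found (searched from offset %d)",
            child$node_name, cursor), node = child$node_name, offset = cursor)
        }
        content_start <- m[["end"]] + 1L
      } else {
        content_start <- cursor
      }
      if (!is.null(child$end_pattern)) {
        e <- regex_find(child$end_pattern, text, content_start, hi)
        if (is.null(e)) {
          mb_parse_failure(sprintf(
            "end pattern of node '%s' not found (searched from offset %d)",
            child$node_name, content_start), node = child$node_name,
            offset = content_start)
        }
        content_end <- e[["start"]] - 1L
        cursor <- e[["end"]] + 1L
      } else {
        sib <- next_sibling_start(children, i, text, content_start, hi)
        content_end <- if (is.null(sib)) hi else sib[["start"]] - 1L
        cursor <- content_end + 1L
      }
      out[[length(out) + 1L]] <- parse_node_span(child, text, content_start, content_end)
    }
  }
  out
}

#' Parse a structured flat file against a text schema
#'
#' Parses the document into a tree mirroring the schema hierarchy. Repeatable
#' nodes are instantiated once per start-pattern match, in input order. Every
#' node carries `span_start`/`span_end` attributes (1-based character offsets
#' of its content in the input, delimiters excluded), so span coverage and
#' boundary placement are checkable.
#'
#' @param schema An `mb_text_schema` (see [build_text_schema()]).
#' @param text Document text.
#' @return An `mb_doctree`.
#' @export
parse_flat_file <- function(schema, text) {
  stopifnot(inherits(schema, "mb_text_schema"))
  if (is.null(text) || !is_string(text)) mb_bad_argument("`text` must be a single string")
  root <- schema$root
  lo <- 1L
  hi <- nchar(text)
  if (!is.null(root$start_pattern)) {
    m <- regex_find(root$start_pattern, text, lo, hi)
    if (is.null(m)) {
      mb_parse_failure(sprintf("root start pattern never matches (offset %d)", lo),
                       node = root$node_name, offset = lo)
    }
    lo <- m[["end"]] + 1L
  }
  if (!is.null(root$end_pattern)) {
    e <- regex_find(root$end_pattern, text, lo, hi)
    if (is.null(e)) {
      mb_parse_failure(sprintf("root end pattern not found (offset %d)", lo),
                       node = root$node_name, offset = lo)
    }
    hi <- e[["start"]] - 1L
  }
  parse_node_span(root, text, lo, hi)
}
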