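# Generic XML wrapper: parse a DTD (or a minimal XSD subset) into a schema
# model, enumerate element/attribute paths for classification, and extract
# values from document instances by path.

#' Parse an XML schema into a schema model
#'
#' The primary dialect is the DTD (`<!ELEMENT ...>` / `<!ATTLIST ...>`
#' declarations); a minimal XSD subset (nested `xs:element`, `xs:sequence` /
#' `xs:choice`, `xs:attribute`) is also accepted. Unsupported constructs
#' (entities, notations, conditional sections, mixed content beyond
#' `#PCDATA`) are rejected loudly rather than silently dropped.
#'
#' @param schema_text Schema text.
#' @param dialect `"dtd"` or `"xsd-subset"`.
#' @return An object of class `mb_xml_schema` with fields `root_element` and
#'   `elements` (name -> declaration with `children` (name + cardinality),
#'   `attributes`, `recursive` flag).
#' @export
parse_schema <- function(schema_text, dialect = c("dtd", "xsd-subset")) {
  dialect <- match.arg(dialect)
  if (!is_string(schema_text) || !nzchar(trimws(schema_text))) {
    mb_bad_argument("schema_text must be a non-empty string")
  }
  if (dialect == "dtd") parse_dtd(schema_text) else parse_xsd_subset(schema_text)
}

parse_dtd <- function(text) {
  for (bad in c("<!ENTITY", "<!NOTATION", "<![")) {
    at <- regexpr(bad, text, fixed = TRUE)
    if (at[1] != -1L) {
      mb_unsupported(sprintf("unsupported DTD construct '%s' at offset %d",
                             bad, at[1]), offset = at[1])
    }
  }
  # strip comments, keeping offsets only approximately (errors report the
  # offset in the stripped text)
  stripped <- gsub("<!--.*?-->", "", text)

  decl_rx <- "<!(ELEMENT|ATTLIST)\\s+([^>]*?)>"
  ms <- gregexpr(decl_rx, stripped, perl = TRUE)[[1]]
  if (ms[1] == -1L) mb_parse_failure("no DTD declarations found")
  decls <- regmatches(stripped, gregexpr(decl_rx, stripped, perl = TRUE))[[1]]

  # anything outside declarations must be whitespace
  leftover <- stripped
  for (d in decls) leftover <- sub(d, "", leftover, fixed = TRUE)
  if (nzchar(trimws(leftover))) {
    bad_at <- regexpr("\\S", leftover, perl = TRUE)[1]
    mb_parse_failure(sprintf("unparseable DTD content near offset %d: '%s'",
                             bad_at, substr(trimws(leftover), 1, 30)),
                     offset = bad_at)
  }

  elements <- list()
  order <- character()
  for (k in seq_along(decls)) {
    d <- decls[[k]]
    offset <- ms[k]
    body <- sub("^<!(ELEMENT|ATTLIST)\\s+", "", sub(">$", "", d), perl = TRUE)
    kind <- sub("^<!(ELEMENT|ATTLIST).*$", "\\1", d, perl = TRUE)
    parts <- strsplit(trimws(body), "\\s+", perl = TRUE)[[1]]
    nm <- parts[1]
    rest <- trimws(sub(paste0("^", nm), "", trimws(body)))
    if (kind == "ELEMENT") {
      ch <- parse_content_model(rest, nm, offset)
      if (is.null(elements[[nm]])) order <- c(order, nm)
      prev <- elements[[nm]]
      elements[[nm]] <- list(name = nm, children = ch,
                             attributes = prev$attributes %||% character())
    } else {
      attrs <- parse_attlist(rest, nm, offset)
      if (is.null(elements[[nm]])) {
        order <- c(order, nm)
        elements[[nm]] <- list(name = nm, children = list(), attributes = attrs)
      } else {
        elements[[nm]]$attributes <- c(elements[[nm]]$attributes, attrs)
      }
    }
  }

  finish_schema_model(elements, order, dialect = "dtd")
}

# Parse a DTD content model into an ordered list of (name, cardinality)
# child references. Groups are flattened; declaration order is preserved.
parse_content_model <- function(model, elem, offset) {
  model <- trimws(model)
  if (model %in% c("EMPTY", "(#PCDATA)", "ANY")) return(list())
  if (grepl("#PCDATA", model, fixed = TRUE)) {
    mb_unsupported(sprintf(
      "mixed content beyond (#PCDATA) on element '%s' (offset %d) is not supported",
      elem, offset))
  }
  inner <- model
  # strip outer parens/cardinality, then flatten nested groups
  inner <- gsub("[()]", ",", inner)
  toks <- strsplit(inner, "[,|]", perl = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  out <- list()
  for (t in toks) {
    card <- ""
    if (grepl("[?*+]$", t)) {
      card <- substr(t, nchar(t), nchar(t))
      t <- substr(t, 1, nchar(t) - 1L)
    }
    if (!grepl("^[A-Za-z_:][A-Za-z0-9._:-]*$", t)) {
      mb_parse_failure(sprintf("invalid child reference '%s' in element '%s' (offset %d)",
                               t, elem, offset), offset = offset)
    }
    out[[length(out) + 1L]] <- list(name = t, cardinality = card)
  }
  out
}

parse_attlist <- function(rest, elem, offset) {
  toks <- strsplit(trimws(rest), "\\s+", perl = TRUE)[[1]]
  attrs <- character()
  i <- 1L
  while (i <= length(toks)) {
    nm <- toks[i]
    if (i + 1L > length(toks)) {
      mb_parse_failure(sprintf("truncated ATTLIST for '%s' (offset %d)", elem, offset),
                       offset = offset)
    }
    type <- toks[i + 1L]
    # enumerated types arrive as (a|b|c) in one token after whitespace split
    i <- i + 2L
    # default declaration: #REQUIRED / #IMPLIED / #FIXED "v" / "v"
    if (i <= length(toks) && toks[i] == "#FIXED") i <- i + 2L
    else if (i <= length(toks) && grepl("^#", toks[i])) i <- i + 1L
    else if (i <= length(toks) && grepl("^[\"']", toks[i])) i <- i + 1L
    attrs <- c(attrs, nm)
  }
  attrs
}

finish_schema_model <- function(elements, order, dialect) {
  referenced <- unique(unlist(lapply(elements, function(e) {
    vapply(e$children, `[[`, "", "name")
  })))
  for (r in referenced) {
    if (is.null(elements[[r]])) {
      mb_invalid(sprintf("child element '%s' is referenced but never declared", r))
    }
  }
  roots <- setdiff(order, referenced)
  if (!length(roots)) {
    mb_invalid("no root element: every declared element is referenced (cycle)")
  }
  root <- roots[[1]]

  # flag recursion (declarations reachable from themselves)
  recursive <- character()
  for (nm in order) {
    seen <- character()
    frontier <- vapply(elements[[nm]]$children, `[[`, "", "name")
    while (length(frontier)) {
      nxt <- frontier[[1]]
      frontier <- frontier[-1]
      if (nxt == nm) {
        recursive <- c(recursive, nm)
        break
      }
      if (nxt %in% seen) next
      seen <- c(seen, nxt)
      frontier <- c(frontier, vapply(elements[[nxt]]$children, `[[`, "", "name"))
    }
  }
  structure(list(root_element = root, elements = elements, order = order,
                 recursive = unique(recursive), dialect = dialect),
            class = "mb_xml_schema")
}

parse_xsd_subset <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    mb_parse_failure(paste("XSD parse error:", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "schema") mb_parse_failure("not an XSD document")
  elements <- list()
  order <- character()
  walk <- function(el) {
    nm <- xml2::xml_attr(el, "name")
    if (is.na(nm)) mb_unsupported("xs:element without a name (references are not supported)")
    kids <- xml2::xml_find_all(
      el, "./*[local-name()='complexType']/*[local-name()='sequence' or local-name()='choice']/*[local-name()='element']")
    attrs <- xml2::xml_attr(
      xml2::xml_find_all(el, "./*[local-name()='complexType']/*[local-name()='attribute']"),
      "name")
    child_names <- list()
    for (k in kids) {
      cn <- xml2::xml_attr(k, "name")
      card <- ""
      if (identical(xml2::xml_attr(k, "maxOccurs"), "unbounded")) card <- "*"
      child_names[[length(child_names) + 1L]] <- list(name = cn, cardinality = card)
    }
    if (is.null(elements[[nm]])) order <<- c(order, nm)
    elements[[nm]] <<- list(name = nm, children = child_names,
                            attributes = as.character(attrs))
    for (k in kids) walk(k)
  }
  tops <- xml2::xml_find_all(doc, "./*[local-name()='element']")
  if (!length(tops)) mb_parse_failure("XSD declares no top-level element")
  for (t in tops) walk(t)
  finish_schema_model(elements, order, dialect = "xsd-subset")
}

#' Enumerate classified element and attribute paths
#'
#' Walks the schema model depth-first in declaration order and emits one
#' absolute path per declared element and attribute reachable from the root.
#' Recursive declarations are expanded to depth 1 and marked.
#'
#' @param model An `mb_xml_schema`.
#' @return A data.frame with columns `path`, `kind` (`"element"` /
#'   `"attribute"`), `leaf_name`, `recursive`.
#' @export
enumerate_paths <- function(model) {
  stopifnot(inherits(model, "mb_xml_schema"))
  rows <- list()
  emit <- function(path, kind, leaf, recursive = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(path = path, kind = kind,
                                             leaf_name = leaf,
                                             recursive = recursive,
                                             stringsAsFactors = FALSE)
  }
  walk <- function(name, prefix, stack) {
    path <- paste0(prefix, "/", name)
    if (name %in% stack) {
      emit(path, "element", name, recursive = TRUE)
      return()
    }
    emit(path, "element", name)
    decl <- model$elements[[name]]
    for (a in decl$attributes) emit(paste0(path, "@", a), "attribute", a)
    for (ch in decl$children) walk(ch$name, path, c(stack, name))
  }
  walk(model$root_element, "", character())
  do.call(rbind, rows)
}

#' Extract values from an XML document by path
#'
#' Paths use element names only, rooted at the document element
#' (`"/genbank_db/genbank_entry/origin"`); a trailing `@name` addresses an
#' attribute. Element text is the whitespace-normalized concatenation of the
#' element's direct text children. Values are returned in document order;
#' an absent path yields an empty character vector.
#'
#' @param document_text XML text (or a file path understood by
#'   [xml2::read_xml()]).
#' @param path Absolute element path, optionally ending in `@attr`.
#' @return Character vector of values.
#' @export
extract_xml <- function(document_text, path) {
  doc <- tryCatch(xml2::read_xml(document_text), error = function(e) {
    mb_parse_failure(paste("malformed XML document:", conditionMessage(e)))
  })
  ns <- tryCatch(unname(unlist(xml2::xml_ns(doc))), error = function(e) character())
  real_ns <- setdiff(ns, "http://www.w3.org/XML/1998/namespace")
  if (length(real_ns)) mb_unsupported("namespaced XML documents are not supported")
  if (!is_string(path) || !startsWith(path, "/")) {
    mb_bad_path(sprintf("path must be absolute, got '%s'", as.character(path)[1]))
  }
  attr_name <- NULL
  if (grepl("@", path, fixed = TRUE)) {
    attr_name <- sub("^.*@", "", path)
    path <- sub("@.*$", "", path)
  }
  steps <- split_path(path)
  if (!length(steps)) mb_bad_path("'/' alone does not address an element")
  xpath <- paste0("/", paste(steps, collapse = "/"))
  nodes <- xml2::xml_find_all(doc, xpath)
  if (!is.null(attr_name)) {
    vals <- xml2::xml_attr(nodes, attr_name)
    return(as.character(vals[!is.na(vals)]))
  }
  vapply(nodes, function(n) {
    squish(paste0(xml2::xml_text(xml2::xml_find_all(n, "./text()")), collapse = ""))
  }, "")
}
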