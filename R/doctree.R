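# Uniform internal document tree shared by the text and XML wrappers.
# A node is a plain list: element name, leaf text, attribute map, ordered
# children. Interior nodes aggregate the text of their descendants.

#' Construct a document-tree node
#'
#' @param node Element name.
#' @param text Leaf text content (ignored for interior nodes).
#' @param attributes Named list of attribute values.
#' @param children Ordered list of child `mb_doctree` nodes.
#' @return An object of class `mb_doctree`.
#' @export
doc_node <- function(node, text = "", attributes = list(), children = list()) {
  if (!is_string(node) || !nzchar(node)) mb_bad_argument("node name must be a non-empty string")
  structure(list(node = node, text = text, attributes = attributes,
                 children = children),
            class = "mb_doctree")
}

node_text <- function(tree) {
  if (!length(tree$children)) return(tree$text)
  paste0(vapply(tree$children, node_text, ""), collapse = "")
}

split_path <- function(path) {
  if (!is_string(path) || !startsWith(path, "/")) {
    mb_bad_path(sprintf("path must be absolute ('/a/b/c'), got '%s'", as.character(path)[1]))
  }
  if (identical(path, "/")) return(character())
  steps <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (any(!nzchar(steps)) || any(grepl("[\\[\\]@]", steps, perl = TRUE))) {
    mb_bad_path(sprintf("malformed path '%s': empty or non-name step", path))
  }
  steps
}

#' Extract node text by absolute path
#'
#' Paths are absolute name-step paths (`"/genbank_db/genbank_entry/origin"`);
#' the first step must name the root. `"/"` addresses the root itself.
#' Matching nodes are returned in document order; an unmatched path yields an
#' empty character vector.
#'
#' @param tree An `mb_doctree`.
#' @param path Absolute path string.
#' @return Character vector of node texts (interior nodes aggregate their
#'   leaves).
#' @export
tree_extract <- function(tree, path) {
  stopifnot(inherits(tree, "mb_doctree"))
  steps <- split_path(path)
  if (!length(steps)) return(node_text(tree))
  if (!identical(steps[[1]], tree$node)) return(character())
  nodes <- list(tree)
  for (s in steps[-1]) {
    nxt <- list()
    for (n in nodes) {
      for (ch in n$children) if (identical(ch$node, s)) nxt[[length(nxt) + 1L]] <- ch
    }
    nodes <- nxt
    if (!length(nodes)) return(character())
  }
  vapply(nodes, node_text, "")
}

#' Render a document tree as XML
#'
#' Elements only, UTF-8; the optional export of the parsed representation.
#'
#' @param tree An `mb_doctree`.
#' @return XML text.
#' @export
tree_to_xml <- function(tree) {
  stopifnot(inherits(tree, "mb_doctree"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  render <- function(n) {
    if (!length(n$children)) {
      sprintf("<%s>%s</%s>", n$node, esc(n$text), n$node)
    } else {
      paste0("<", n$node, ">",
             paste0(vapply(n$children, render, ""), collapse = ""),
             "</", n$node, ">")
    }
  }
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n", render(tree), "\n")
}

#' @export
print.mb_doctree <- function(x, ...) {
  show <- function(n, depth) {
    pad <- strrep("  ", depth)
    if (!length(n$children)) {
      txt <- n$text
      if (nchar(txt) > 40) txt <- paste0(substr(txt, 1, 37), "...")
      cat(sprintf("%s<%s> %s\n", pad, n$node, txt))
    } else {
      cat(sprintf("%s<%s>\n", pad, n$node))
      for (ch in n$children) show(ch, depth + 1L)
    }
  }
  show(x, 0L)
  invisible(x)
}
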