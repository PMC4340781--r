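# Shared helpers for building small registries and synthetic callables.

# A minimal one-source registry: `src` exposing element `Thing` with one
# simple operation `Poke` -> generic op `poke` -> components$obj$poke().
tiny_registry <- function(components = new_component_registry()) {
  register_component(components, "obj", list(poke = function(x) paste0("poked:", x)))
  reg <- new_registry()
  register_source(
    reg,
    data_source_entry("src", "web_service", "tiny fixture source"),
    elements = list(data_element("Thing", attributes = c("x"),
                                 user_operations = "Poke")),
    mappings = list(api_mapping("poke", "src",
                                callable_descriptor("obj", "poke", c("x")),
                                result_key = "poked")),
    operations = list(user_operation("Poke", "src", "Thing", "simple", "poke")))
  list(registry = reg, components = components)
}

# Generate a random pure function of `k` string parameters together with the
# metadata needed to register and call it. Uses the current RNG stream.
random_pure_callable <- function(k) {
  salt <- paste(sample(letters, 6), collapse = "")
  fn <- switch(as.character(k),
    "0" = local({ s <- salt; function() paste0("c0-", s) }),
    "1" = local({ s <- salt; function(a1) paste0("c1-", s, "-", a1) }),
    "2" = local({ s <- salt; function(a1, a2) paste0("c2-", s, "-", a1, "-", a2) }),
    "3" = local({ s <- salt; function(a1, a2, a3) paste0("c3-", s, "-", a1, "-", a2, "-", a3) }))
  specs <- if (k == 0) list() else lapply(seq_len(k), function(j) {
    list(name = paste0("a", j), type = "string")
  })
  args <- if (k == 0) list() else as.list(paste0("v", seq_len(k), "-", salt))
  names(args) <- vapply(specs, `[[`, "", "name")
  list(fn = fn, specs = specs, args = args)
}

# Build a random HTML element tree (divs/spans/paragraphs under <body>),
# planting `value` in one random leaf; returns the html text and the tag
# path of the planted leaf under the element-ordinal convention.
random_planted_html <- function(value, max_depth = 3) {
  # tags libxml2's lenient parser nests without restructuring
  tags <- c("div", "span", "b")
  build <- function(depth) {
    tag <- sample(tags, 1)
    n_kids <- if (depth >= max_depth) 0L else sample(0:3, 1)
    if (n_kids == 0L) {
      list(html = sprintf("<%s>leaf %d</%s>", tag, sample(99, 1), tag),
           tag = toupper(tag), paths = list())
    } else {
      kids <- lapply(seq_len(n_kids), function(i) build(depth + 1L))
      inner <- paste(vapply(kids, `[[`, "", "html"), collapse = "")
      paths <- list()
      for (i in seq_along(kids)) {
        step <- sprintf("%s[%d]", kids[[i]]$tag, i - 1L)
        for (p in kids[[i]]$paths) paths[[length(paths) + 1L]] <- c(step, p)
        if (!length(kids[[i]]$paths)) paths[[length(paths) + 1L]] <- step
      }
      list(html = sprintf("<%s>%s</%s>", tag, inner, tag),
           tag = toupper(tag), paths = paths)
    }
  }
  tree <- build(1L)
  # choose one leaf path and rebuild with the value planted there
  leafs <- Filter(function(p) TRUE, tree$paths)
  if (!length(leafs)) {
    return(list(html = sprintf("<html><body><div>%s</div></body></html>", value),
                path = "HTML[0]/BODY[0]/DIV[0]"))
  }
  target <- sample(leafs, 1)[[1]]
  # recorded paths are relative to the generated root element, which itself
  # sits at ordinal 0 under <body>
  full_target <- c(sprintf("%s[0]", tree$tag), target)
  doc <- xml2::read_html(paste0("<html><body>", tree$html, "</body></html>"))
  cur <- xml2::xml_child(xml2::xml_root(doc), "body")
  for (s in full_target) {
    m <- regmatches(s, regexec("^([A-Z]+)\\[([0-9]+)\\]$", s))[[1]]
    cur <- xml2::xml_children(cur)[[as.integer(m[3]) + 1L]]
  }
  # plant in the element reached (clearing any children makes it a leaf)
  xml2::xml_text(cur) <- value
  list(html = as.character(doc),
       path = paste(c("HTML[0]", "BODY[0]", full_target), collapse = "/"))
}
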