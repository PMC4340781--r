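# Generic API ontology: a typed metadata registry of data sources, their data
# elements, biologist-level user operations, and the mappings from generic
# operations to concrete source callables.

SOURCE_TYPES <- c("xml", "flat_file", "web_page", "web_service",
                  "relational_database", "ftp", "email", "ontology")

#' Describe a data source
#'
#' A `data_source_entry` names one integrated source, classifies its access
#' type, and carries an opaque connection configuration that is handed
#' unchanged to the matching generic wrapper.
#'
#' @param name Unique source identifier.
#' @param source_type One of `"xml"`, `"flat_file"`, `"web_page"`,
#'   `"web_service"`, `"relational_database"`, `"ftp"`, `"email"`,
#'   `"ontology"`.
#' @param description Free-text description.
#' @param connection_config Named list handed to the wrapper; keys must be
#'   non-empty strings.
#' @return An object of class `mb_source_entry`.
#' @export
data_source_entry <- function(name, source_type, description = "",
                              connection_config = list()) {
  if (!is_string(name) || !nzchar(name)) mb_bad_argument("source `name` must be a non-empty string")
  if (!is_string(source_type) || !source_type %in% SOURCE_TYPES) {
    mb_bad_argument(sprintf("unknown source_type '%s' (expected one of: %s)",
                            source_type, paste(SOURCE_TYPES, collapse = ", ")))
  }
  if (length(connection_config)) {
    keys <- names(connection_config)
    if (is.null(keys) || any(!nzchar(keys))) {
      mb_invalid("connection_config keys must be non-empty strings")
    }
  }
  structure(list(name = name, source_type = source_type,
                 description = description,
                 connection_config = connection_config),
            class = "mb_source_entry")
}

#' Describe a data element of a source
#'
#' Data elements are the domain terms a biologist operates on (Gene, Protein,
#' File, ...). Each carries named attribute descriptors, the user operations
#' applicable to it, and an optional client-side display hint that is stored
#' and returned verbatim, never executed.
#'
#' @param element_name Domain term, e.g. `"Protein"`.
#' @param attributes Attribute descriptors: a character vector of names
#'   (semantic type defaults to `"string"`) or a list of `list(name, type)`.
#' @param user_operations Character vector of operation names applicable to
#'   this element.
#' @param ui_hint Optional `list(component, method)` client descriptor, e.g.
#'   `list(component = "imp.ui.StringInput", method = "getValue")`.
#' @return An object of class `mb_element`.
#' @export
data_element <- function(element_name, attributes = list(),
                         user_operations = character(), ui_hint = NULL) {
  if (!is_string(element_name) || !nzchar(element_name)) {
    mb_bad_argument("element_name must be a non-empty string")
  }
  if (is.character(attributes)) {
    attributes <- lapply(attributes, function(a) list(name = a, type = "string"))
  }
  attributes <- lapply(attributes, function(a) {
    if (is_string(a)) a <- list(name = a, type = "string")
    if (!is_string(a$name) || !nzchar(a$name)) mb_invalid("attribute names must be non-empty")
    list(name = a$name, type = a$type %||% "string")
  })
  anames <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(anames)) {
    mb_invalid(sprintf("duplicate attribute name(s) on element '%s': %s",
                       element_name, paste(unique(anames[duplicated(anames)]), collapse = ", ")))
  }
  structure(list(element_name = element_name, attributes = attributes,
                 user_operations = as.character(user_operations),
                 ui_hint = ui_hint),
            class = "mb_element")
}

#' Describe a concrete source callable
#'
#' A callable descriptor identifies a method on a live component (by the
#' component's registry reference and method name) together with its fully
#' typed, ordered parameter list. The call constructor invokes it by runtime
#' introspection.
#'
#' @param target_ref Identifier of a registered component (or one registered
#'   later at execution time, e.g. by an Initialize/Create generic operation).
#' @param method_name Method to call on the target; `""` if the target itself
#'   is a function.
#' @param parameter_specs Ordered list of `list(name, type)` (a character
#'   vector of names is accepted, typed `"string"`).
#' @param return_type Semantic type of the return value.
#' @return An object of class `mb_callable`.
#' @export
callable_descriptor <- function(target_ref, method_name = "",
                                parameter_specs = list(),
                                return_type = "string") {
  if (!is_string(target_ref) || !nzchar(target_ref)) {
    mb_bad_argument("target_ref must be a non-empty string")
  }
  if (is.character(parameter_specs)) {
    parameter_specs <- lapply(parameter_specs, function(p) list(name = p, type = "string"))
  }
  parameter_specs <- lapply(parameter_specs, function(p) {
    if (is_string(p)) p <- list(name = p, type = "string")
    if (!is_string(p$name) || !nzchar(p$name)) mb_invalid("parameter names must be non-empty")
    if (!is_string(p$type) || !nzchar(p$type)) {
      mb_invalid(sprintf("parameter '%s' lacks a semantic type", p$name))
    }
    list(name = p$name, type = p$type)
  })
  structure(list(target_ref = target_ref, method_name = method_name,
                 parameter_specs = parameter_specs, return_type = return_type),
            class = "mb_callable")
}

#' Map a generic operation to a concrete callable
#'
#' @param generic_op Generic operation name (e.g. `"Access-read"`).
#' @param source_name Owning source.
#' @param callable A [callable_descriptor()].
#' @param result_key Context name under which the return value is stored.
#' @param result_type Semantic type of the return value.
#' @param register_result_as Optional component-registry id under which the
#'   return value is registered as a new live target (how Initialize/Create
#'   style operations publish the objects later calls are made on).
#' @param aliases Additional generic-op names resolving to this mapping.
#' @return An object of class `mb_mapping`.
#' @export
api_mapping <- function(generic_op, source_name, callable, result_key,
                        result_type = "string", register_result_as = NULL,
                        aliases = character()) {
  if (!is_string(generic_op) || !nzchar(generic_op)) mb_bad_argument("generic_op must be a non-empty string")
  if (!inherits(callable, "mb_callable")) mb_bad_argument("callable must be a callable_descriptor()")
  if (!is_string(result_key) || !nzchar(result_key)) mb_bad_argument("result_key must be a non-empty string")
  structure(list(generic_op = generic_op, source_name = source_name,
                 callable = callable, result_key = result_key,
                 result_type = result_type,
                 register_result_as = register_result_as,
                 aliases = as.character(aliases)),
            class = "mb_mapping")
}

#' Describe a biologist-level user operation
#'
#' Simple operations route to one generic operation; complex operations
#' reference a state-machine model that issues a sequence of generic calls.
#'
#' @param operation_name Operation name, e.g. `"FetchData"`.
#' @param source_name Owning source.
#' @param element_name Data element the operation applies to.
#' @param kind `"simple"` or `"complex"`.
#' @param target For simple operations a generic-op name; for complex ones a
#'   state-machine model identifier such as `"FetchData.xml"`.
#' @return An object of class `mb_user_op`.
#' @export
user_operation <- function(operation_name, source_name, element_name,
                           kind = c("simple", "complex"), target) {
  kind <- match.arg(kind)
  for (f in c(operation_name, source_name, element_name, target)) {
    if (!is_string(f) || !nzchar(f)) mb_bad_argument("user_operation fields must be non-empty strings")
  }
  structure(list(operation_name = operation_name, source_name = source_name,
                 element_name = element_name, kind = kind, target = target),
            class = "mb_user_op")
}

#' Create an empty ontology registry
#'
#' The registry is the single authority mapping source names to their
#' classified metadata: elements, user operations, generic-API mappings, and
#' state-machine model documents.
#'
#' @return An environment of class `mb_registry`.
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$sources <- list()   # name -> list(entry, elements, mappings, operations)
  reg$order <- character()
  reg$models <- list()    # model_id -> model XML text
  class(reg) <- "mb_registry"
  reg
}

#' @export
print.mb_registry <- function(x, ...) {
  cat(sprintf("<mb_registry: %d source(s), %d state-machine model(s)>\n",
              length(x$order), length(x$models)))
  invisible(x)
}

op_key <- function(operation_name, element_name) paste0(operation_name, "\r", element_name)

#' Register a data source with all its metadata
#'
#' Registration is atomic: the entry, its elements, generic-API mappings,
#' user operations, and any state-machine models are validated as a whole and
#' either all become visible or none do.
#'
#' @param registry An [new_registry()] object.
#' @param entry A [data_source_entry()].
#' @param elements List of [data_element()].
#' @param mappings List of [api_mapping()].
#' @param operations List of [user_operation()].
#' @param models Named list of state-machine model XML texts, keyed by model
#'   id; complex operation targets must resolve here or among previously
#'   registered models.
#' @return The source name, invisibly.
#' @export
register_source <- function(registry, entry, elements = list(),
                            mappings = list(), operations = list(),
                            models = list()) {
  stopifnot(inherits(registry, "mb_registry"))
  if (!inherits(entry, "mb_source_entry")) mb_bad_argument("entry must be a data_source_entry()")
  name <- entry$name
  if (name %in% registry$order) {
    mb_conflict(sprintf("source '%s' is already registered", name), source = name)
  }

  el_names <- vapply(elements, function(e) e$element_name, "")
  if (anyDuplicated(el_names)) mb_invalid("duplicate element names in registration")
  el_index <- stats::setNames(elements, el_names)

  # Index mappings under canonical names and any aliases; (generic_op, source)
  # pairs must be unique, aliases included.
  map_index <- list()
  for (m in mappings) {
    if (!inherits(m, "mb_mapping")) mb_bad_argument("mappings must be api_mapping() objects")
    if (!identical(m$source_name, name)) {
      mb_invalid(sprintf("mapping '%s' names source '%s', not '%s'",
                         m$generic_op, m$source_name, name))
    }
    for (key in unique(c(m$generic_op, m$aliases))) {
      if (!is.null(map_index[[key]])) {
        mb_conflict(sprintf("duplicate generic-op mapping '%s' for source '%s'", key, name))
      }
      map_index[[key]] <- m
    }
  }

  new_models <- registry$models
  if (length(models)) {
    if (is.null(names(models)) || any(!nzchar(names(models)))) {
      mb_bad_argument("`models` must be a named list keyed by model id")
    }
    for (id in names(models)) new_models[[id]] <- models[[id]]
  }

  op_index <- list()
  for (op in operations) {
    if (!inherits(op, "mb_user_op")) mb_bad_argument("operations must be user_operation() objects")
    if (!identical(op$source_name, name)) {
      mb_invalid(sprintf("operation '%s' names source '%s', not '%s'",
                         op$operation_name, op$source_name, name))
    }
    if (!op$element_name %in% c(el_names, "*")) {
      mb_invalid(sprintf("operation '%s' targets unregistered element '%s'",
                         op$operation_name, op$element_name))
    }
    if (op$kind == "simple" && is.null(map_index[[op$target]])) {
      mb_invalid(sprintf("simple operation '%s' targets unregistered generic op '%s'",
                         op$operation_name, op$target))
    }
    if (op$kind == "complex" && is.null(new_models[[op$target]])) {
      mb_invalid(sprintf("complex operation '%s' targets unknown state-machine model '%s'",
                         op$operation_name, op$target))
    }
    key <- op_key(op$operation_name, op$element_name)
    if (!is.null(op_index[[key]])) {
      mb_conflict(sprintf(
        "ambiguous registration: operation '%s' declared twice for element '%s'",
        op$operation_name, op$element_name))
    }
    op_index[[key]] <- op
  }

  # Every user operation listed on an element must resolve.
  declared_ops <- unlist(lapply(operations, `[[`, "operation_name"))
  for (e in elements) {
    missing <- setdiff(e$user_operations, declared_ops)
    if (length(missing)) {
      mb_invalid(sprintf("element '%s' lists unresolvable user operation(s): %s",
                         e$element_name, paste(missing, collapse = ", ")))
    }
  }

  # Commit (all-or-nothing: nothing above mutated the registry).
  registry$sources[[name]] <- list(entry = entry, elements = el_index,
                                   mappings = map_index, operations = op_index)
  registry$order <- c(registry$order, name)
  registry$models <- new_models
  invisible(name)
}

#' List registered sources
#'
#' @param registry A registry.
#' @return Character vector of source names in registration order.
#' @export
get_ds_list <- function(registry) {
  stopifnot(inherits(registry, "mb_registry"))
  registry$order
}

#' Retrieve the classified metadata of a source
#'
#' Returns the complete metadata tree for one source: every classified
#' element with its attributes, user operations and display hint — exactly
#' what was registered, nothing more.
#'
#' @param registry A registry.
#' @param source_name Registered source name.
#' @return A list with fields `name`, `source_type`, `description`, and
#'   `elements` (each element carrying `attributes`, `user_operations`,
#'   `ui_hint`).
#' @export
get_ds_metadata <- function(registry, source_name) {
  stopifnot(inherits(registry, "mb_registry"))
  src <- registry$sources[[source_name]]
  if (is.null(src)) {
    mb_not_found(sprintf("source '%s' is not registered", source_name),
                 source = source_name)
  }
  list(
    name = src$entry$name,
    source_type = src$entry$source_type,
    description = src$entry$description,
    elements = lapply(unname(src$elements), function(e) {
      list(element_name = e$element_name,
           attributes = e$attributes,
           user_operations = e$user_operations,
           ui_hint = e$ui_hint)
    })
  )
}

#' Route a user operation to its target
#'
#' Looks up the registered user operation for the triple and answers either
#' with the state-machine model id (complex operations) or a distinguished
#' direct-mapping answer naming the generic op (simple operations). An exact
#' element match beats a wildcard (`"*"`) registration.
#'
#' @param registry A registry.
#' @param operation_name,source_name,element_name The operation triple.
#' @return `list(kind = "complex", target = <model id>)` or
#'   `list(kind = "simple", target = <generic op>)`.
#' @export
lookup_state_machine_model <- function(registry, operation_name, source_name,
                                       element_name) {
  stopifnot(inherits(registry, "mb_registry"))
  src <- registry$sources[[source_name]]
  if (is.null(src)) {
    mb_not_found(sprintf("source '%s' is not registered", source_name))
  }
  op <- src$operations[[op_key(operation_name, element_name)]] %||%
    src$operations[[op_key(operation_name, "*")]]
  if (is.null(op)) {
    mb_not_found(sprintf("no operation '%s' registered for (%s, %s)",
                         operation_name, source_name, element_name))
  }
  list(kind = op$kind, target = op$target)
}

#' Resolve a generic operation to its concrete mapping
#'
#' @param registry A registry.
#' @param generic_op Generic operation name (aliases resolve too).
#' @param source_name Owning source.
#' @return The registered [api_mapping()].
#' @export
resolve_mapping <- function(registry, generic_op, source_name) {
  stopifnot(inherits(registry, "mb_registry"))
  src <- registry$sources[[source_name]]
  if (is.null(src)) {
    mb_not_found(sprintf("no mapping for ('%s', '%s'): source not registered",
                         generic_op, source_name))
  }
  m <- src$mappings[[generic_op]]
  if (is.null(m)) {
    mb_not_found(sprintf("no mapping registered for ('%s', '%s')",
                         generic_op, source_name))
  }
  m
}

#' Fetch a registered state-machine model document
#'
#' @param registry A registry.
#' @param model_id Model identifier, e.g. `"FetchData.xml"`.
#' @return The model XML text.
#' @export
get_model_text <- function(registry, model_id) {
  txt <- registry$models[[model_id]]
  if (is.null(txt)) mb_not_found(sprintf("state-machine model '%s' is not registered", model_id))
  txt
}

# ---- canonical serialization ------------------------------------------------

mapping_to_list <- function(m) {
  list(generic_op = m$generic_op, source_name = m$source_name,
       callable = list(target_ref = m$callable$target_ref,
                       method_name = m$callable$method_name,
                       parameter_specs = m$callable$parameter_specs,
                       return_type = m$callable$return_type),
       result_key = m$result_key, result_type = m$result_type,
       register_result_as = m$register_result_as, aliases = I(m$aliases))
}

#' Serialize a registry to canonical JSON
#'
#' The serialization is canonical — fixed field order, keyed collections
#' sorted by key — so that serialize/deserialize/serialize is byte-identical.
#'
#' @param registry A registry.
#' @param file Optional path to write to.
#' @return JSON text (invisibly when `file` is given).
#' @export
registry_to_json <- function(registry, file = NULL) {
  stopifnot(inherits(registry, "mb_registry"))
  srcs <- lapply(registry$order, function(name) {
    src <- registry$sources[[name]]
    # mappings deduplicated back to canonical objects, sorted by generic_op
    maps <- list(); seen <- character()
    for (key in sort(names(src$mappings))) {
      m <- src$mappings[[key]]
      if (m$generic_op %in% seen) next
      seen <- c(seen, m$generic_op)
      maps[[length(maps) + 1L]] <- mapping_to_list(m)
    }
    ops <- lapply(src$operations[sort(names(src$operations))], function(op) {
      list(operation_name = op$operation_name, source_name = op$source_name,
           element_name = op$element_name, kind = op$kind, target = op$target)
    })
    els <- lapply(src$elements[sort(names(src$elements))], function(e) {
      list(element_name = e$element_name, attributes = e$attributes,
           user_operations = I(e$user_operations), ui_hint = e$ui_hint)
    })
    list(entry = list(name = src$entry$name,
                      source_type = src$entry$source_type,
                      description = src$entry$description,
                      connection_config = src$entry$connection_config),
         elements = unname(els), mappings = maps, operations = unname(ops))
  })
  models <- registry$models[order(names(registry$models))]
  doc <- list(format = "metabind-registry", version = 1L,
              sources = srcs, models = models)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null",
                           digits = NA)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Load a registry from its canonical JSON serialization
#'
#' @param json JSON text or a file path.
#' @return An `mb_registry`.
#' @export
registry_from_json <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, "metabind-registry")) {
    mb_parse_failure("not a metabind registry document")
  }
  reg <- new_registry()
  reg$models <- lapply(doc$models, identity)
  for (s in doc$sources) {
    entry <- data_source_entry(s$entry$name, s$entry$source_type,
                               s$entry$description %||% "",
                               s$entry$connection_config %||% list())
    elements <- lapply(s$elements, function(e) {
      data_element(e$element_name, e$attributes %||% list(),
                   unlist(e$user_operations) %||% character(),
                   e$ui_hint)
    })
    mappings <- lapply(s$mappings, function(m) {
      api_mapping(m$generic_op, m$source_name,
                  callable_descriptor(m$callable$target_ref,
                                      m$callable$method_name %||% "",
                                      m$callable$parameter_specs %||% list(),
                                      m$callable$return_type %||% "string"),
                  m$result_key, m$result_type %||% "string",
                  m$register_result_as,
                  unlist(m$aliases) %||% character())
    })
    operations <- lapply(s$operations, function(op) {
      user_operation(op$operation_name, op$source_name, op$element_name,
                     op$kind, op$target)
    })
    register_source(reg, entry, elements, mappings, operations, models = list())
  }
  reg
}
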