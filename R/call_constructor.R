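# Data-source call constructor: bind a generic operation to its concrete
# callable using the ontology mapping and the execution context, construct
# missing parameters via registered recipes, and invoke the callable by
# runtime introspection.
#
# Parameter-filling precedence, per parameter:
#   1. explicit binding directive (from the state-machine action),
#   2. context value matching by name AND type,
#   3. unique context value matching by type (two candidates -> ambiguity
#      error rather than silent first-match),
#   4. a registered constructor recipe for the semantic type.
# Type compatibility is exact string match plus declared widenings.

#' Create a component registry of live targets
#'
#' The component registry holds the live objects concrete calls are made on,
#' keyed by the `target_ref` of callable descriptors. Initialize/Create
#' style generic operations may publish their results here as new targets.
#'
#' @return An environment of class `mb_components`.
#' @export
new_component_registry <- function() {
  comps <- new.env(parent = emptyenv())
  comps$targets <- list()
  class(comps) <- "mb_components"
  comps
}

#' Register (or hot-swap) a live component
#'
#' Replacing the object behind an existing reference is the supported
#' hot-swap path: mappings and clients keep working unchanged while
#' subsequent calls hit the new implementation.
#'
#' @param components An `mb_components` registry.
#' @param ref Target reference string.
#' @param object A function, or a named list/environment of functions.
#' @return The registry, invisibly.
#' @export
register_component <- function(components, ref, object) {
  stopifnot(inherits(components, "mb_components"))
  if (!is_string(ref) || !nzchar(ref)) mb_bad_argument("component ref must be a non-empty string")
  components$targets[[ref]] <- object
  invisible(components)
}

#' @rdname register_component
#' @export
get_component <- function(components, ref) {
  obj <- components$targets[[ref]]
  if (is.null(obj)) {
    mb_abort("mb_resolution_error", sprintf("no component registered under '%s'", ref))
  }
  obj
}

type_compatible <- function(have, want, widenings = list()) {
  identical(have, want) || identical(have, "any") || identical(want, "any") ||
    (want %in% names(widenings) && have %in% widenings[[want]])
}

#' Bind concrete arguments for a mapping from an execution context
#'
#' Fills each declared parameter of the mapping's callable by the documented
#' precedence and reports which rule fired for every argument, plus a log of
#' any parameter construction performed.
#'
#' @param mapping An [api_mapping()].
#' @param context An [init_context()] execution context.
#' @param directives Named binding directives (`list(kind = "context", key =
#'   ...)` or `list(kind = "literal", value = ...)`), normally carried by the
#'   state-machine action.
#' @param recipes Named list: semantic type -> `function(context)`
#'   constructing a value of that type from context components.
#' @param widenings Named list: target type -> character vector of types
#'   accepted in its place.
#' @return An object of class `mb_binding_report` with `bound_args`,
#'   `provenance` (one of `directive`, `context-by-name`, `context-by-type`,
#'   `constructed`), `construction_steps`.
#' @export
bind_parameters <- function(mapping, context, directives = list(),
                            recipes = list(), widenings = list()) {
  stopifnot(inherits(mapping, "mb_mapping"), inherits(context, "mb_context"))
  specs <- mapping$callable$parameter_specs
  bound <- vector("list", length(specs))
  prov <- character(length(specs))
  steps <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    d <- directives[[spec$name]]
    if (!is.null(d)) {
      if (identical(d$kind, "literal")) {
        bound[[i]] <- d$value
        prov[i] <- "directive"
        next
      }
      key <- d$key %||% spec$name
      if (!context_has(context, key)) {
        mb_abort("mb_binding_error",
                 sprintf("directive for parameter '%s' references missing context key '%s'",
                         spec$name, key), parameter = spec$name)
      }
      bound[[i]] <- context_get(context, key)
      prov[i] <- "directive"
      next
    }
    if (context_has(context, spec$name) &&
        type_compatible(context_type(context, spec$name), spec$type, widenings)) {
      bound[[i]] <- context_get(context, spec$name)
      prov[i] <- "context-by-name"
      next
    }
    candidates <- Filter(function(nm) {
      type_compatible(context_type(context, nm), spec$type, widenings)
    }, context_names(context))
    if (length(candidates) == 1L) {
      bound[[i]] <- context_get(context, candidates[[1]])
      prov[i] <- "context-by-type"
      next
    }
    if (length(candidates) > 1L) {
      mb_abort("mb_ambiguity_error",
               sprintf("parameter '%s' (type '%s') matches %d context values by type (%s) and none by name",
                       spec$name, spec$type, length(candidates),
                       paste(candidates, collapse = ", ")),
               parameter = spec$name, candidates = candidates)
    }
    recipe <- recipes[[spec$type]]
    if (!is.null(recipe)) {
      bound[[i]] <- recipe(context)
      prov[i] <- "constructed"
      steps[[length(steps) + 1L]] <- list(parameter = spec$name, type = spec$type)
      next
    }
    mb_abort("mb_binding_error",
             sprintf(paste0("cannot bind parameter '%s' (type '%s'): no directive, ",
                            "no context value by name+type, no unique value by type, ",
                            "no constructor recipe"),
                     spec$name, spec$type),
             parameter = spec$name,
             tried = c("directive", "context-by-name", "context-by-type", "constructed"))
  }
  structure(list(bound_args = bound, provenance = prov,
                 construction_steps = steps,
                 parameter_names = vapply(specs, `[[`, "", "name")),
            class = "mb_binding_report")
}

#' Invoke a concrete callable by introspection
#'
#' Resolves the descriptor's target in the component registry and its method
#' by name, checks arity against the declared signature before calling, and
#' wraps any raised error with the descriptor identity.
#'
#' @param descriptor A [callable_descriptor()].
#' @param args Ordered argument values (a list or an `mb_binding_report`).
#' @param components An `mb_components` registry.
#' @return The call's return value.
#' @export
invoke_callable <- function(descriptor, args, components) {
  stopifnot(inherits(descriptor, "mb_callable"))
  if (inherits(args, "mb_binding_report")) args <- args$bound_args
  target <- get_component(components, descriptor$target_ref)
  fn <- if (is.function(target)) {
    if (nzchar(descriptor$method_name)) {
      mb_abort("mb_resolution_error",
               sprintf("target '%s' is a bare function but method '%s' was requested",
                       descriptor$target_ref, descriptor$method_name))
    }
    target
  } else {
    m <- tryCatch(target[[descriptor$method_name]], error = function(e) NULL)
    if (!is.function(m)) {
      mb_abort("mb_resolution_error",
               sprintf("no method '%s' on component '%s'",
                       descriptor$method_name, descriptor$target_ref))
    }
    m
  }
  fmls <- formals(fn)
  if (!"..." %in% names(fmls) && length(args) != length(fmls)) {
    mb_abort("mb_resolution_error",
             sprintf("arity mismatch calling %s.%s: %d argument(s) for %d parameter(s)",
                     descriptor$target_ref, descriptor$method_name,
                     length(args), length(fmls)))
  }
  tryCatch(do.call(fn, unname(args)), error = function(e) {
    mb_abort("mb_invocation_error",
             sprintf("invocation of %s.%s failed: %s", descriptor$target_ref,
                     descriptor$method_name, conditionMessage(e)),
             parent = e)
  })
}

#' Translate a generic operation into a concrete call and execute it
#'
#' The full dynamic-invocation path: resolve the (generic op, source)
#' mapping in the registry, bind arguments from the context, invoke the
#' concrete callable, store the result in the context under the mapping's
#' result key (and publish it as a new component when the mapping says so).
#'
#' @param registry The ontology registry.
#' @param generic_op Generic operation name.
#' @param source_name Source owning the mapping.
#' @param context Execution context (mutated: gains the result entry).
#' @param components Component registry of live targets.
#' @param directives,recipes,widenings See [bind_parameters()].
#' @return A list `(result, report)` with the call result and the
#'   [bind_parameters()] report.
#' @export
translate_and_call <- function(registry, generic_op, source_name, context,
                               components, directives = list(),
                               recipes = list(), widenings = list()) {
  mapping <- withCallingHandlers(
    resolve_mapping(registry, generic_op, source_name),
    mb_not_found_error = function(e) {
      mb_not_found(sprintf("generic op '%s' on source '%s': %s",
                           generic_op, source_name, conditionMessage(e)))
    })
  report <- bind_parameters(mapping, context, directives, recipes, widenings)
  result <- invoke_callable(mapping$callable, report, components)
  context_put(context, mapping$result_key, result, mapping$result_type)
  if (!is.null(mapping$register_result_as)) {
    register_component(components, mapping$register_result_as, result)
  }
  list(result = result, report = report)
}

#' Binder closure over a registry and component set
#'
#' Adapts [translate_and_call()] to the `(op, context, directives)` binder
#' signature expected by [execute_model()].
#'
#' @param registry Ontology registry.
#' @param source_name Source whose mappings the binder resolves against.
#' @param components Component registry.
#' @param recipes,widenings See [bind_parameters()].
#' @return A binder function.
#' @export
make_registry_binder <- function(registry, source_name, components,
                                 recipes = list(), widenings = list()) {
  force(registry); force(source_name); force(components)
  function(op, context, directives = list()) {
    translate_and_call(registry, op, source_name, context, components,
                       directives = directives, recipes = recipes,
                       widenings = widenings)$result
  }
}
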