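# XML state-machine models with Event-Condition-Action transitions.
#
# Dialect (one model per document):
#   <stateMachine id="FetchData.xml" initial="s0">
#     <state name="s0">
#       <transition event="step" guard="true" to="s1">
#         <action op="webserviceInitialization" resultKey="object0">
#           <bind param="query" from="context" key="query"/>
#           <bind param="format" from="literal" value="raw"/>
#         </action>
#       </transition>
#     </state>
#     <state name="s1" final="true" onError="failed"/>
#   </stateMachine>
#
# Transition semantics follow ECA rules (ON event IF guard DO action): when
# an event arrives, the outgoing transitions of the current state are
# examined in declaration order and the first whose event matches and whose
# guard evaluates true fires. After each fired action a default "step" event
# is auto-emitted so purely sequential models run without an external event
# source; external events may be injected for reactive models.
#
# The guard language is a small closed algebra over the execution context:
#   true | false | exists(key) | key == 'literal' | matches(key, 'pattern')
# combined with `and`, `or`, `not` and parentheses. Guard evaluation is
# side-effect free.

# ---- guard language --------------------------------------------------------

guard_tokenize <- function(src) {
  toks <- list()
  i <- 1L
  n <- nchar(src)
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",")) { push(ch, ch); i <- i + 1L; next }
    if (ch == "'") {
      j <- i + 1L
      while (j <= n && substr(src, j, j) != "'") j <- j + 1L
      if (j > n) mb_parse_failure(sprintf("unterminated string literal in guard '%s'", src))
      push("string", substr(src, i + 1L, j - 1L))
      i <- j + 1L
      next
    }
    if (substr(src, i, i + 1L) == "==") { push("==", "=="); i <- i + 2L; next }
    m <- regex_find("^[A-Za-z_][A-Za-z0-9_.-]*", src, i, n)
    if (!is.null(m) && m[["start"]] == i) {
      word <- substr(src, m[["start"]], m[["end"]])
      type <- if (word %in% c("and", "or", "not", "true", "false",
                              "exists", "matches")) word else "ident"
      push(type, word)
      i <- m[["end"]] + 1L
      next
    }
    mb_parse_failure(sprintf("unexpected character '%s' at %d in guard '%s'", ch, i, src))
  }
  toks
}

parse_guard <- function(src) {
  toks <- guard_tokenize(src)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else "<eof>"
  take <- function(type = NULL) {
    if (pos > length(toks)) mb_parse_failure(sprintf("guard '%s' ends unexpectedly", src))
    t <- toks[[pos]]
    if (!is.null(type) && t$type != type) {
      mb_parse_failure(sprintf("expected '%s' but found '%s' in guard '%s'",
                               type, t$value, src))
    }
    pos <<- pos + 1L
    t
  }
  parse_expr <- function() {
    node <- parse_term()
    while (peek() == "or") {
      take("or")
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (peek() == "and") {
      take("and")
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    switch(peek(),
      "not" = { take("not"); list(op = "not", arg = parse_factor()) },
      "(" = { take("("); e <- parse_expr(); take(")"); e },
      "true" = { take("true"); list(op = "const", value = TRUE) },
      "false" = { take("false"); list(op = "const", value = FALSE) },
      "exists" = {
        take("exists"); take("(")
        k <- take("ident")$value
        take(")")
        list(op = "exists", key = k)
      },
      "matches" = {
        take("matches"); take("(")
        k <- take("ident")$value
        take(",")
        p <- take("string")$value
        take(")")
        list(op = "matches", key = k, pattern = p)
      },
      "ident" = {
        k <- take("ident")$value
        take("==")
        v <- take("string")$value
        list(op = "eq", key = k, value = v)
      },
      mb_parse_failure(sprintf("unexpected token in guard '%s'", src))
    )
  }
  ast <- parse_expr()
  if (pos <= length(toks)) {
    mb_parse_failure(sprintf("trailing tokens in guard '%s'", src))
  }
  ast
}

eval_guard_ast <- function(ast, context) {
  switch(ast$op,
    const = ast$value,
    and = eval_guard_ast(ast$lhs, context) && eval_guard_ast(ast$rhs, context),
    or = eval_guard_ast(ast$lhs, context) || eval_guard_ast(ast$rhs, context),
    not = !eval_guard_ast(ast$arg, context),
    exists = context_has(context, ast$key),
    eq = context_has(context, ast$key) &&
      identical(as.character(context_get(context, ast$key)), ast$value),
    matches = context_has(context, ast$key) &&
      grepl(ast$pattern, as.character(context_get(context, ast$key)), perl = TRUE),
    mb_invalid(sprintf("unknown guard node '%s'", ast$op))
  )
}

#' Evaluate a guard expression against an execution context
#'
#' @param guard Guard source text (see the dialect description in
#'   [load_model()]).
#' @param context An execution context ([new_context()]).
#' @return Logical scalar; evaluation never mutates the context.
#' @export
eval_guard <- function(guard, context) {
  eval_guard_ast(parse_guard(guard), context)
}

# ---- model load / validate / build -----------------------------------------

#' Load and validate a state-machine model
#'
#' Parses a model document in the package's state-machine XML dialect,
#' checks the structural invariants (exactly one initial state, at least one
#' final state, transition endpoints exist, no two transitions out of one
#' state share event and guard, guards parse) and fails with the complete
#' diagnostic list if any is violated. Whether an action's generic op is
#' resolvable is a property of the registry at execution time, not of the
#' model, so it is checked then.
#'
#' @param model_text Model XML text (or a file path).
#' @return An object of class `mb_sm_model`.
#' @export
load_model <- function(model_text) {
  doc <- tryCatch(xml2::read_xml(model_text), error = function(e) {
    mb_parse_failure(paste("state-machine model parse error:", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "stateMachine") {
    mb_parse_failure("not a stateMachine document")
  }
  model_id <- xml2::xml_attr(doc, "id")
  initial <- xml2::xml_attr(doc, "initial")
  states <- list()
  transitions <- list()
  for (sx in xml2::xml_find_all(doc, "./state")) {
    nm <- xml2::xml_attr(sx, "name")
    states[[nm]] <- list(name = nm,
                         final = identical(xml2::xml_attr(sx, "final"), "true"),
                         on_error = xml2::xml_attr(sx, "onError") %|na|% NULL)
    for (tx in xml2::xml_find_all(sx, "./transition")) {
      ax <- xml2::xml_find_first(tx, "./action")
      action <- NULL
      if (!inherits(ax, "xml_missing")) {
        directives <- list()
        for (bx in xml2::xml_find_all(ax, "./bind")) {
          pname <- xml2::xml_attr(bx, "param")
          from <- xml2::xml_attr(bx, "from")
          directives[[pname]] <- if (identical(from, "literal")) {
            list(kind = "literal", value = xml2::xml_attr(bx, "value"))
          } else {
            list(kind = "context", key = xml2::xml_attr(bx, "key"))
          }
        }
        action <- list(op = xml2::xml_attr(ax, "op"),
                       result_key = xml2::xml_attr(ax, "resultKey") %|na|% "result",
                       directives = directives)
      }
      transitions[[length(transitions) + 1L]] <- list(
        from = nm,
        event = xml2::xml_attr(tx, "event") %|na|% "step",
        guard = xml2::xml_attr(tx, "guard") %|na|% "true",
        action = action,
        to = xml2::xml_attr(tx, "to"))
    }
  }
  model <- structure(list(model_id = model_id, initial = initial,
                          states = states, transitions = transitions),
                     class = "mb_sm_model")
  diags <- validate_model(model)
  errors <- diags[vapply(diags, `[[`, "", "level") == "error"]
  if (length(errors)) {
    mb_invalid(paste0("invalid state-machine model:\n",
                      paste(vapply(errors, `[[`, "", "message"), collapse = "\n")),
               diagnostics = diags)
  }
  model
}

#' Validate a state-machine model
#'
#' @param model An `mb_sm_model` (validation also accepts structurally
#'   complete plain lists, which is how [build_model()] uses it).
#' @return A list of diagnostics, each `list(level, where, message)`; empty
#'   iff every invariant holds. Unreachable states are warnings, structural
#'   violations are errors.
#' @export
validate_model <- function(model) {
  diags <- list()
  say <- function(level, where, msg) {
    diags[[length(diags) + 1L]] <<- list(level = level, where = where, message = msg)
  }
  snames <- names(model$states)
  if (is.null(model$initial) || is.na(model$initial)) {
    say("error", "<model>", "no initial state declared")
  } else if (!model$initial %in% snames) {
    say("error", model$initial, sprintf("initial state '%s' does not exist", model$initial))
  }
  finals <- snames[vapply(model$states, function(s) isTRUE(s$final), TRUE)]
  if (!length(finals)) say("error", "<model>", "no final state declared")
  seen_keys <- character()
  for (k in seq_along(model$transitions)) {
    tr <- model$transitions[[k]]
    where <- sprintf("transition %d (%s -> %s)", k, tr$from, tr$to %||% "?")
    if (is.null(tr$to) || is.na(tr$to) || !tr$to %in% snames) {
      say("error", where, sprintf("dangling to_state '%s' in %s", tr$to, where))
    }
    if (!tr$from %in% snames) {
      say("error", where, sprintf("transition from unknown state '%s'", tr$from))
    }
    g_ok <- tryCatch({ parse_guard(tr$guard); TRUE },
                     error = function(e) conditionMessage(e))
    if (!isTRUE(g_ok)) say("error", where, sprintf("guard does not parse: %s", g_ok))
    key <- paste(tr$from, tr$event, tr$guard, sep = "\r")
    if (key %in% seen_keys) {
      say("error", where,
          sprintf("duplicate (event '%s', guard '%s') out of state '%s'",
                  tr$event, tr$guard, tr$from))
    }
    seen_keys <- c(seen_keys, key)
  }
  for (s in snames) {
    oe <- model$states[[s]]$on_error
    if (!is.null(oe) && !oe %in% snames) {
      say("error", s, sprintf("onError state '%s' of '%s' does not exist", oe, s))
    }
  }
  # reachability from the initial state
  if (!is.null(model$initial) && model$initial %in% snames) {
    reach <- model$initial
    repeat {
      grow <- unique(unlist(lapply(model$transitions, function(tr) {
        if (tr$from %in% reach) c(tr$to, model$states[[tr$from]]$on_error) else NULL
      })))
      grow <- setdiff(grow[!is.na(grow)], reach)
      if (!length(grow)) break
      reach <- c(reach, grow)
    }
    for (s in setdiff(snames, reach)) {
      say("warning", s, sprintf("state '%s' is unreachable from the initial state", s))
    }
  }
  diags
}

#' Serialize a state-machine model
#'
#' Deterministic rendering of the model into the XML dialect; serialize then
#' [load_model()] yields a deeply equal model.
#'
#' @param model An `mb_sm_model`.
#' @param file Optional path to write to.
#' @return XML text.
#' @export
serialize_model <- function(model, file = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub('"', "&quot;", x, fixed = TRUE)
    x
  }
  lines <- c(sprintf('<stateMachine id="%s" initial="%s">',
                     esc(model$model_id), esc(model$initial)))
  for (s in model$states) {
    attrs <- sprintf(' name="%s"', esc(s$name))
    if (isTRUE(s$final)) attrs <- paste0(attrs, ' final="true"')
    if (!is.null(s$on_error)) attrs <- paste0(attrs, sprintf(' onError="%s"', esc(s$on_error)))
    trs <- Filter(function(tr) tr$from == s$name, model$transitions)
    if (!length(trs)) {
      lines <- c(lines, sprintf("  <state%s/>", attrs))
      next
    }
    lines <- c(lines, sprintf("  <state%s>", attrs))
    for (tr in trs) {
      head <- sprintf('    <transition event="%s" guard="%s" to="%s"',
                      esc(tr$event), esc(tr$guard), esc(tr$to))
      if (is.null(tr$action)) {
        lines <- c(lines, paste0(head, "/>"))
      } else {
        lines <- c(lines, paste0(head, ">"))
        a <- tr$action
        ahead <- sprintf('      <action op="%s" resultKey="%s"', esc(a$op), esc(a$result_key))
        if (!length(a$directives)) {
          lines <- c(lines, paste0(ahead, "/>"))
        } else {
          lines <- c(lines, paste0(ahead, ">"))
          for (pn in names(a$directives)) {
            d <- a$directives[[pn]]
            lines <- c(lines, if (d$kind == "literal") {
              sprintf('        <bind param="%s" from="literal" value="%s"/>',
                      esc(pn), esc(d$value))
            } else {
              sprintf('        <bind param="%s" from="context" key="%s"/>',
                      esc(pn), esc(d$key))
            })
          }
          lines <- c(lines, "      </action>")
        }
        lines <- c(lines, "    </transition>")
      }
    }
    lines <- c(lines, "  </state>")
  }
  lines <- c(lines, "</stateMachine>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Build a state-machine model programmatically
#'
#' @param description A list with `model_id`, `initial`, `states` (list of
#'   `list(name, final, on_error)`), `transitions` (list of `list(from,
#'   event, guard, action, to)`).
#' @return A list `(model, text)`: the validated model and its deterministic
#'   serialization.
#' @export
build_model <- function(description) {
  states <- list()
  for (s in description$states) {
    if (is_string(s)) s <- list(name = s)
    states[[s$name]] <- list(name = s$name, final = isTRUE(s$final),
                             on_error = s$on_error %||% NULL)
  }
  transitions <- lapply(description$transitions, function(tr) {
    list(from = tr$from, event = tr$event %||% "step",
         guard = tr$guard %||% "true", action = tr$action, to = tr$to)
  })
  model <- structure(list(model_id = description$model_id %||% "model.xml",
                          initial = description$initial,
                          states = states, transitions = transitions),
                     class = "mb_sm_model")
  diags <- validate_model(model)
  errors <- diags[vapply(diags, `[[`, "", "level") == "error"]
  if (length(errors)) {
    mb_abort("mb_build_error",
             paste0("cannot build model:\n",
                    paste(vapply(errors, `[[`, "", "message"), collapse = "\n")),
             diagnostics = diags)
  }
  list(model = model, text = serialize_model(model))
}

#' Build a linear model executing a sequence of generic operations
#'
#' Produces the canonical shape of a complex user operation: n+1 states in a
#' line, each transition firing one generic action on the auto-advance
#' "step" event.
#'
#' @param ops Character vector of generic operation names (or a list of
#'   `list(op, result_key, directives)`).
#' @param model_id Model identifier.
#' @param result_keys Optional character vector of result keys (defaults to
#'   `result1..resultN`).
#' @return A list `(model, text)` as for [build_model()].
#' @export
build_linear_model <- function(ops, model_id = "model.xml", result_keys = NULL) {
  if (!length(ops)) {
    mb_abort("mb_build_error", "a linear model requires at least one operation")
  }
  acts <- lapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (is_string(o)) o <- list(op = o)
    list(op = o$op,
         result_key = o$result_key %||% result_keys[i] %||% paste0("result", i),
         directives = o$directives %||% list())
  })
  n <- length(acts)
  states <- c(lapply(seq_len(n), function(i) list(name = paste0("s", i - 1L))),
              list(list(name = paste0("s", n), final = TRUE)))
  transitions <- lapply(seq_len(n), function(i) {
    list(from = paste0("s", i - 1L), event = "step", guard = "true",
         action = acts[[i]], to = paste0("s", i))
  })
  build_model(list(model_id = model_id, initial = "s0",
                   states = states, transitions = transitions))
}

# ---- execution -------------------------------------------------------------

#' Execute a state-machine model
#'
#' Starts in the initial state and repeatedly: takes the next event (an
#' injected one, else the auto-advance `"step"`), evaluates the guards of the
#' current state's outgoing transitions in declaration order, fires the first
#' whose event matches and whose guard holds, executes its action through
#' `binder`, stores the result in the context under the action's result key,
#' and moves on. Terminates on reaching a final state. Every fired
#' transition is recorded in the context trace.
#'
#' If an action fails and its state declares an `onError` transition target,
#' execution continues there; otherwise an execution error carrying the
#' trace is raised. If no transition fires for an event, a stall error is
#' raised.
#'
#' @param model An `mb_sm_model` from [load_model()] or [build_model()].
#' @param context An execution context ([new_context()]); mutated in place.
#' @param binder Function `(op, context, directives)` invoked for each
#'   action; its return value is the action result (see
#'   [make_registry_binder()]).
#' @param events Optional character vector of injected external events,
#'   consumed in order before auto-advance resumes.
#' @param max_steps Safety bound on fired transitions.
#' @return The final context, invisibly.
#' @export
execute_model <- function(model, context, binder, events = character(),
                          max_steps = 10000L) {
  stopifnot(inherits(model, "mb_sm_model"), is.function(binder))
  state <- model$initial
  queue <- as.character(events)
  fired <- 0L
  while (!isTRUE(model$states[[state]]$final)) {
    if (fired >= max_steps) {
      mb_abort("mb_execution_error",
               sprintf("execution exceeded %d transitions", max_steps),
               trace = context_trace(context))
    }
    event <- if (length(queue)) {
      e <- queue[[1]]
      queue <- queue[-1]
      e
    } else "step"
    out <- Filter(function(tr) tr$from == state, model$transitions)
    chosen <- NULL
    guard_result <- NA
    for (tr in out) {
      if (!identical(tr$event, event)) next
      g <- eval_guard(tr$guard, context)
      if (isTRUE(g)) {
        chosen <- tr
        guard_result <- TRUE
        break
      }
    }
    if (is.null(chosen)) {
      mb_abort("mb_stall_error",
               sprintf("no transition fires from state '%s' on event '%s'",
                       state, event),
               state = state, event = event, trace = context_trace(context))
    }
    outcome <- "ok"
    if (!is.null(chosen$action)) {
      a <- chosen$action
      res <- tryCatch(binder(a$op, context, a$directives), error = function(e) e)
      if (inherits(res, "error")) {
        oe <- model$states[[state]]$on_error
        trace_append(context, state, event, TRUE, a$op, "error")
        if (is.null(oe)) {
          mb_abort("mb_execution_error",
                   sprintf("action '%s' failed in state '%s': %s",
                           a$op, state, conditionMessage(res)),
                   trace = context_trace(context), parent = res)
        }
        state <- oe
        fired <- fired + 1L
        next
      }
      # a registry binder already stores the result (typed) under the
      # mapping's result key; only store here if the model's key adds to that
      if (!context_has(context, a$result_key) ||
          !identical(context_get(context, a$result_key), res)) {
        context_put(context, a$result_key, res)
      }
      trace_append(context, state, event, TRUE, a$op, "ok")
    } else {
      trace_append(context, state, event, TRUE, NA_character_, "ok")
    }
    state <- chosen$to
    fired <- fired + 1L
  }
  invisible(context)
}
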