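fetch_model_text <- function() {
  build_linear_model(
    list(list(op = "webserviceInitialization", result_key = "object0"),
         list(op = "webserviceConstructor", result_key = "object1"),
         list(op = "Access-Read", result_key = "fetchResult")),
    model_id = "FetchData.xml")$text
}

recording_binder <- function(log) {
  function(op, context, directives) {
    log$ops <- c(log$ops, op)
    paste0("ran:", op)
  }
}

test_that("model loading validates structure and round-trips serialization", {
  model <- load_model(fetch_model_text())
  ops <- vapply(Filter(function(tr) !is.null(tr$action), model$transitions),
                function(tr) tr$action$op, "")
  expect_identical(ops, c("webserviceInitialization", "webserviceConstructor",
                          "Access-Read"))
  expect_identical(serialize_model(model), fetch_model_text())
  expect_equal(load_model(serialize_model(model)), model)

  # structural violations are collected, not reported one at a time
  bad <- paste(
    '<stateMachine id="x" initial="ghost">',
    '  <state name="a"><transition event="step" guard="true" to="nowhere"/></state>',
    "</stateMachine>", sep = "\n")
  err <- expect_error(load_model(bad), class = "mb_validation_error")
  msgs <- vapply(err$diagnostics, `[[`, "", "message")
  expect_true(any(grepl("initial state", msgs)))
  expect_true(any(grepl("dangling to_state", msgs)))
  expect_true(any(grepl("no final state", msgs)))
})

test_that("validation diagnoses unreachable states and duplicate rules", {
  built <- build_model(list(
    model_id = "d.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE), "orphan"),
    transitions = list(list(from = "a", to = "b"))))
  diags <- validate_model(built$model)
  expect_identical(vapply(diags, `[[`, "", "level"), "warning")
  expect_match(diags[[1]]$message, "orphan")

  expect_error(build_model(list(
    model_id = "dup.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE)),
    transitions = list(list(from = "a", to = "b"),
                       list(from = "a", to = "b")))),
    class = "mb_build_error")
  expect_error(build_linear_model(character()), class = "mb_build_error")
})

test_that("guard language evaluates its closed atom algebra without side effects", {
  ctx <- init_context(list(db = "pdb", q = "pdb:1e12"))
  before <- as.list(ctx$values)
  expect_true(eval_guard("true", ctx))
  expect_false(eval_guard("false", ctx))
  expect_true(eval_guard("exists(db)", ctx))
  expect_false(eval_guard("exists(absent)", ctx))
  expect_true(eval_guard("db == 'pdb'", ctx))
  expect_true(eval_guard("matches(q, '^pdb:')", ctx))
  expect_true(eval_guard("not false and (db == 'pdb' or false)", ctx))
  expect_false(eval_guard("not exists(db)", ctx))
  expect_error(eval_guard("db ==", ctx), class = "mb_parse_error")
  expect_error(eval_guard("db == 'x' extra", ctx), class = "mb_parse_error")
  expect_identical(as.list(ctx$values), before)
  expect_identical(nrow(context_trace(ctx)), 0L)
})

test_that("linear models execute actions in order, equal to direct invocation", {
  for (n in c(1L, 5L, 20L)) {
    ops <- sprintf("op%02d", seq_len(n))
    model <- build_linear_model(as.list(ops))$model
    log <- new.env()
    log$ops <- character()
    ctx <- init_context()
    execute_model(model, ctx, recording_binder(log))
    # oracle: invoking the binder directly in sequence
    oracle_log <- new.env()
    oracle_log$ops <- character()
    oracle_ctx <- init_context()
    oracle <- recording_binder(oracle_log)
    for (i in seq_len(n)) {
      res <- oracle(ops[i], oracle_ctx, list())
      context_put(oracle_ctx, paste0("result", i), res)
    }
    expect_identical(log$ops, oracle_log$ops)
    expect_identical(lapply(context_names(ctx), function(nm) context_get(ctx, nm)),
                     lapply(context_names(oracle_ctx),
                            function(nm) context_get(oracle_ctx, nm)))
    tr <- context_trace(ctx)
    expect_identical(nrow(tr), n)
    expect_identical(tr$action, ops)
    expect_identical(tr$state, sprintf("s%d", seq_len(n) - 1L))
  }
})

test_that("execution is deterministic for a fixed model, context, and binder", {
  model <- load_model(fetch_model_text())
  binder <- function(op, context, directives) paste0("v:", op)
  run <- function() {
    ctx <- init_context(list(query = "q"))
    execute_model(model, ctx, binder)
    list(values = as.list(ctx$values), trace = context_trace(ctx))
  }
  expect_identical(run(), run())
})

test_that("guards gate transitions; a false guard stalls execution", {
  built <- build_model(list(
    model_id = "g.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE)),
    transitions = list(list(from = "a", guard = "false",
                            action = list(op = "never", result_key = "r",
                                          directives = list()),
                            to = "b"))))
  log <- new.env()
  log$ops <- character()
  err <- expect_error(execute_model(built$model, init_context(),
                                    recording_binder(log)),
                      class = "mb_stall_error")
  expect_identical(log$ops, character())
  expect_identical(err$state, "a")

  # guard chooses among transitions in declaration order
  routed <- build_model(list(
    model_id = "r.xml", initial = "a",
    states = list("a", list(name = "yes", final = TRUE),
                  list(name = "no", final = TRUE)),
    transitions = list(
      list(from = "a", guard = "mode == 'fast'", to = "yes"),
      list(from = "a", guard = "true", to = "no"))))
  ctx <- init_context(list(mode = "fast"))
  execute_model(routed$model, ctx, recording_binder(new.env()))
  expect_identical(context_trace(ctx)$state, "a")
  ctx2 <- init_context(list(mode = "slow"))
  execute_model(routed$model, ctx2, function(op, context, directives) NULL)
  expect_identical(nrow(context_trace(ctx2)), 1L)
})

test_that("action failures take the onError transition or carry the trace", {
  failing_binder <- function(op, context, directives) {
    if (op == "boom") stop("exploded") else paste0("ok:", op)
  }
  rescued <- build_model(list(
    model_id = "e.xml", initial = "a",
    states = list(list(name = "a", on_error = "fallback"),
                  list(name = "b", final = TRUE),
                  list(name = "fallback", final = TRUE)),
    transitions = list(list(from = "a",
                            action = list(op = "boom", result_key = "r",
                                          directives = list()),
                            to = "b"))))
  ctx <- init_context()
  execute_model(rescued$model, ctx, failing_binder)
  tr <- context_trace(ctx)
  expect_identical(tr$outcome, "error")

  unrescued <- build_model(list(
    model_id = "e2.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE)),
    transitions = list(list(from = "a",
                            action = list(op = "boom", result_key = "r",
                                          directives = list()),
                            to = "b"))))
  err <- expect_error(execute_model(unrescued$model, init_context(), failing_binder),
                      class = "mb_execution_error")
  expect_s3_class(err$trace, "data.frame")
  expect_identical(err$trace$action, "boom")
})

test_that("injected external events are consumed before auto-advance", {
  reactive <- build_model(list(
    model_id = "ev.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE)),
    transitions = list(list(from = "a", event = "submit", to = "b"))))
  ctx <- init_context()
  execute_model(reactive$model, ctx, function(op, context, directives) NULL,
                events = "submit")
  expect_identical(context_trace(ctx)$event, "submit")
  expect_error(execute_model(reactive$model, init_context(),
                             function(op, context, directives) NULL),
               class = "mb_stall_error")
})

test_that("binding directives in actions override context lookup", {
  comps <- new_component_registry()
  register_component(comps, "echo", list(f = function(a, b) paste(a, b)))
  reg <- new_registry()
  register_source(reg, data_source_entry("s", "web_service"),
                  mappings = list(api_mapping(
                    "echo.op", "s",
                    callable_descriptor("echo", "f",
                                        list(list(name = "a", type = "string"),
                                             list(name = "b", type = "string"))),
                    result_key = "out")))
  built <- build_model(list(
    model_id = "dir.xml", initial = "a",
    states = list("a", list(name = "b", final = TRUE)),
    transitions = list(list(from = "a",
                            action = list(op = "echo.op", result_key = "out",
                                          directives = list(
                                            a = list(kind = "literal", value = "LIT"),
                                            b = list(kind = "context", key = "other"))),
                            to = "b"))))
  # round trip through serialization keeps directives
  reloaded <- load_model(serialize_model(built$model))
  ctx <- init_context(list(a = "ctx-a", other = "ctx-other"))
  execute_model(reloaded, ctx, make_registry_binder(reg, "s", comps))
  expect_identical(context_get(ctx, "out"), "LIT ctx-other")
})
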