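test_that("binding fills parameters by the documented precedence", {
  mapping <- api_mapping(
    "op", "s",
    callable_descriptor("t", "m",
                        list(list(name = "query", type = "string"),
                             list(name = "fmt", type = "format"),
                             list(name = "made", type = "token"))),
    result_key = "r")
  ctx <- init_context(list(query = "q1", other = "fmt-by-type"),
                      types = c(query = "string", other = "format"))
  recipes <- list(token = function(context) paste0("built-", context_get(context, "query")))
  rep <- bind_parameters(mapping, ctx, recipes = recipes)
  expect_identical(rep$bound_args, list("q1", "fmt-by-type", "built-q1"))
  expect_identical(rep$provenance,
                   c("context-by-name", "context-by-type", "constructed"))
  expect_length(rep$construction_steps, 1)
  expect_identical(rep$construction_steps[[1]]$parameter, "made")

  # explicit directives outrank everything
  rep2 <- bind_parameters(mapping, ctx,
                          directives = list(query = list(kind = "literal",
                                                         value = "override")),
                          recipes = recipes)
  expect_identical(rep2$bound_args[[1]], "override")
  expect_identical(rep2$provenance[1], "directive")
})

test_that("zero-parameter mappings bind to empty argument lists", {
  mapping <- api_mapping("op", "s", callable_descriptor("t", "m"), result_key = "r")
  rep <- bind_parameters(mapping, init_context())
  expect_length(rep$bound_args, 0)
  expect_length(rep$construction_steps, 0)
})

test_that("ambiguous and unresolvable parameters raise classed errors", {
  mapping <- api_mapping(
    "op", "s",
    callable_descriptor("t", "m", list(list(name = "p", type = "seq"))),
    result_key = "r")
  ctx <- init_context(list(x = "a", y = "b"), types = c(x = "seq", y = "seq"))
  err <- expect_error(bind_parameters(mapping, ctx), class = "mb_ambiguity_error")
  expect_setequal(err$candidates, c("x", "y"))

  err2 <- expect_error(bind_parameters(mapping, init_context()),
                       class = "mb_binding_error")
  expect_identical(err2$parameter, "p")
  expect_identical(err2$tried,
                   c("directive", "context-by-name", "context-by-type", "constructed"))
})

test_that("binding is deterministic for fixed mapping and context", {
  mapping <- api_mapping(
    "op", "s",
    callable_descriptor("t", "m", list(list(name = "a", type = "string"),
                                       list(name = "b", type = "string"))),
    result_key = "r")
  ctx <- init_context(list(a = "1", b = "2"))
  expect_identical(bind_parameters(mapping, ctx), bind_parameters(mapping, ctx))
})

test_that("declared type widenings admit compatible context values", {
  mapping <- api_mapping(
    "op", "s",
    callable_descriptor("t", "m", list(list(name = "p", type = "string"))),
    result_key = "r")
  ctx <- init_context(list(p = "acc-1"), types = c(p = "accession"))
  expect_error(bind_parameters(mapping, ctx), class = "mb_binding_error")
  rep <- bind_parameters(mapping, ctx, widenings = list(string = "accession"))
  expect_identical(rep$bound_args[[1]], "acc-1")
})

test_that("introspective invocation resolves, checks arity, and wraps failures", {
  comps <- new_component_registry()
  register_component(comps, "svc", list(
    hello = function(who) paste("hello", who),
    fails = function() stop("inner failure")))
  d <- callable_descriptor("svc", "hello", c("who"))
  expect_identical(invoke_callable(d, list("world"), comps), "hello world")

  expect_error(invoke_callable(callable_descriptor("ghost", "m"), list(), comps),
               class = "mb_resolution_error")
  expect_error(invoke_callable(callable_descriptor("svc", "nope"), list(), comps),
               class = "mb_resolution_error")
  expect_error(invoke_callable(d, list("a", "b"), comps),
               class = "mb_resolution_error")
  err <- expect_error(invoke_callable(callable_descriptor("svc", "fails"), list(), comps),
                      class = "mb_invocation_error")
  expect_match(conditionMessage(err), "svc.fails")
})

test_that("null-method invocation equals direct calls over many repetitions", {
  suite <- make_null_suite()
  comps <- new_component_registry()
  register_component(comps, "null.suite", suite$object)
  d0 <- suite$descriptors$m0
  for (i in 1:1000) invoke_callable(d0, list(), comps)
  direct_env <- suite$env$calls[["m0"]]
  for (i in 1:1000) suite$object$m0()
  expect_identical(suite$env$calls[["m0"]], 2000L)
  expect_identical(invoke_callable(d0, list(), comps), suite$object$m0())
})

test_that("translate_and_call equals direct calls for random pure functions", {
  set.seed(1234)
  comps <- new_component_registry()
  reg <- new_registry()
  cases <- lapply(1:50, function(i) {
    k <- sample(0:3, 1)
    c(random_pure_callable(k), list(id = i, k = k))
  })
  obj <- stats::setNames(lapply(cases, `[[`, "fn"),
                         sprintf("fn%02d", seq_along(cases)))
  register_component(comps, "pure.suite", obj)
  register_source(reg, data_source_entry("pure", "web_service"),
                  mappings = lapply(seq_along(cases), function(i) {
                    api_mapping(sprintf("call%02d", i), "pure",
                                callable_descriptor("pure.suite",
                                                    sprintf("fn%02d", i),
                                                    cases[[i]]$specs),
                                result_key = sprintf("res%02d", i))
                  }))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    ctx <- init_context(cs$args)
    out <- translate_and_call(reg, sprintf("call%02d", i), "pure", ctx, comps)
    expect_identical(out$result, do.call(cs$fn, unname(cs$args)))
    expect_identical(context_get(ctx, sprintf("res%02d", i)), out$result)
  }
  expect_error(translate_and_call(reg, "no-such-op", "pure", init_context(), comps),
               class = "mb_not_found_error")
})

test_that("hot-swapped components change results without re-registration", {
  fix <- tiny_registry()
  ctx <- init_context(list(x = "1"))
  r1 <- translate_and_call(fix$registry, "poke", "src", ctx, fix$components)$result
  expect_identical(r1, "poked:1")
  register_component(fix$components, "obj",
                     list(poke = function(x) paste0("v2:", x)))
  r2 <- translate_and_call(fix$registry, "poke", "src", init_context(list(x = "1")),
                           fix$components)$result
  expect_identical(r2, "v2:1")
})

test_that("create-style mappings publish their results as live targets", {
  mocks <- make_mock_sources(seed = 2)
  ctx <- init_context(list(query = "pdb:1e12", db = "pdb", format = "raw"))
  translate_and_call(mocks$registry, "webserviceConstructor", "EBI", ctx,
                     mocks$components)
  obj1 <- get_component(mocks$components, "object1")
  expect_true(is.function(obj1$fetchData))
  out <- translate_and_call(mocks$registry, "Access-read", "EBI", ctx,
                            mocks$components)
  expect_identical(out$result, mock_protein_record(mocks, "pdb:1e12"))
})
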