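# Local micro-benchmark harness for the dynamic-invocation machinery.
# Absolute milliseconds are hardware-bound and are not compared to anything;
# the reported medians support ordinal/trend assertions only (binding cost
# versus number of constructed parameters, invocation stability across
# arities, model-load time versus model size).

time_median_ms <- function(fn, repetitions, chunks = 20L) {
  time_median_ms_set(list(fn), repetitions, chunks)
}

# Interleaved (round-robin) chunk timing for a set of closures: each chunk
# times every closure once, so slow periods of the host affect all closures
# alike and between-closure comparisons stay fair under load drift.
time_median_ms_set <- function(fns, repetitions, chunks = 20L) {
  iters <- max(1L, ceiling(repetitions / chunks))
  per_chunk <- matrix(0, nrow = chunks, ncol = length(fns))
  for (i in seq_len(chunks)) {
    for (k in seq_along(fns)) {
      fn <- fns[[k]]
      t0 <- Sys.time()
      for (j in seq_len(iters)) fn()
      per_chunk[i, k] <- as.numeric(difftime(Sys.time(), t0, units = "secs")) *
        1000 / iters
    }
  }
  apply(per_chunk, 2, stats::median)
}

#' Run the null-method micro-benchmarks
#'
#' Measures, over chunked repetitions: the median time to bind arguments
#' for null methods `m0..m3` when every parameter must be constructed from
#' recipes; the median introspective invocation time per method; a direct
#' (static) call baseline for `m0`; the per-action scheduling overhead of
#' the state-machine engine; and the model-load time for linear models of
#' 1, 5, 20 and 50 actions.
#'
#' @param repetitions Repetitions for the bind/invoke timings (>= 100).
#' @param seed Seed (used for deterministic setup only; timings are
#'   hardware-dependent by nature).
#' @return An object of class `mb_benchmark`: `binding` and `invocation`
#'   data.frames (`method`, `constructed_params`, `median_ms`),
#'   `static_m0_ms`, `per_action_ms`, `load` data.frame (`actions`,
#'   `median_ms`), `repetitions`.
#' @export
run_benchmarks <- function(repetitions = 1000, seed = 1) {
  if (!is.numeric(repetitions) || repetitions < 100) {
    mb_bad_argument("repetitions must be >= 100")
  }
  repetitions <- as.integer(repetitions)
  suite <- make_null_suite()
  components <- new_component_registry()
  register_component(components, "null.suite", suite$object)

  registry <- new_registry()
  mappings <- lapply(0:3, function(k) {
    api_mapping(paste0("null", k), "bench", suite$descriptors[[k + 1]],
                result_key = paste0("r", k), result_type = "any")
  })
  register_source(registry, data_source_entry("bench", "web_service",
                                              "null-method bench source"),
                  mappings = mappings)

  recipes <- list(
    T1 = function(context) paste0("t1-", "v"),
    T2 = function(context) paste0("t2-", "v"),
    T3 = function(context) paste0("t3-", "v"))
  empty_ctx <- init_context()

  bind_fns <- lapply(0:3, function(k) {
    m <- resolve_mapping(registry, paste0("null", k), "bench")
    function() bind_parameters(m, empty_ctx, recipes = recipes)
  })
  binding <- data.frame(method = paste0("m", 0:3), constructed_params = 0:3,
                        median_ms = time_median_ms_set(bind_fns, repetitions),
                        stringsAsFactors = FALSE)

  invoke_fns <- lapply(0:3, function(k) {
    d <- suite$descriptors[[k + 1]]
    args <- as.list(rep("x", k))
    function() invoke_callable(d, args, components)
  })
  invocation <- data.frame(method = paste0("m", 0:3), constructed_params = 0:3,
                           median_ms = time_median_ms_set(invoke_fns, repetitions),
                           stringsAsFactors = FALSE)

  m0 <- suite$object$m0
  static_m0_ms <- time_median_ms(function() m0(), repetitions)

  # state-machine scheduling overhead per action (null binder)
  sm <- build_linear_model(rep("null0", 10))$model
  null_binder <- function(op, context, directives) NULL
  sched_reps <- max(20L, repetitions %/% 20L)
  per_model_ms <- time_median_ms(function() {
    execute_model(sm, init_context(), null_binder)
  }, sched_reps, chunks = 10L)
  per_action_ms <- per_model_ms / 10

  load_sizes <- c(1L, 5L, 20L, 50L)
  load_reps <- max(20L, repetitions %/% 20L)
  texts <- lapply(load_sizes, function(sz) build_linear_model(rep("null0", sz))$text)
  load <- data.frame(
    actions = load_sizes,
    median_ms = vapply(seq_along(load_sizes), function(i) {
      txt <- texts[[i]]
      time_median_ms(function() load_model(txt), load_reps, chunks = 10L)
    }, 0))

  structure(list(binding = binding, invocation = invocation,
                 static_m0_ms = static_m0_ms, per_action_ms = per_action_ms,
                 load = load, repetitions = repetitions, seed = seed),
            class = "mb_benchmark")
}

#' @export
print.mb_benchmark <- function(x, ...) {
  cat(sprintf("null-method micro-benchmarks (%d repetitions)\n", x$repetitions))
  cat("binding (constructed parameters):\n")
  print(x$binding, row.names = FALSE)
  cat("introspective invocation:\n")
  print(x$invocation, row.names = FALSE)
  cat(sprintf("static m0 call: %.6f ms\n", x$static_m0_ms))
  cat(sprintf("state-machine scheduling: %.4f ms/action\n", x$per_action_ms))
  cat("model load time:\n")
  print(x$load, row.names = FALSE)
  invisible(x)
}

#' Machine-readable benchmark report
#'
#' @param bench An `mb_benchmark`.
#' @param file Optional path to write JSON to.
#' @return JSON text.
#' @export
benchmark_to_json <- function(bench, file = NULL) {
  json <- as.character(jsonlite::toJSON(unclass(bench), auto_unbox = TRUE,
                                        digits = NA, dataframe = "rows"))
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}
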