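test_that("request construction carries every part exactly once", {
  model <- blast_web_model()
  req <- build_request(model, list(QUERY = "ACGTACGT", JOB_TITLE = "t",
                                   DATABASE = "nr"))
  expect_identical(req$method, "POST")
  body <- rawToChar(req$body)
  boundary <- sub("^multipart/form-data; boundary=", "", req$content_type)
  # split with an independent multipart reader: parts delimited by --boundary
  pieces <- strsplit(body, paste0("--", boundary), fixed = TRUE)[[1]]
  pieces <- pieces[nzchar(trimws(pieces)) & trimws(pieces) != "--"]
  names_found <- sub('.*name="([^"]+)".*', "\\1", vapply(pieces, function(p) {
    strsplit(p, "\r\n")[[1]][2]
  }, ""))
  expect_identical(unname(names_found),
                   c("QUERY", "JOB_TITLE", "DATABASE", "QUERYFILE", "db",
                     "BLAST_PROGRAMS"))
  expect_identical(length(pieces),
                   length(model$user_params) + length(model$default_params))
  # boundary appears consistently in header and body
  expect_true(grepl(boundary, req$content_type, fixed = TRUE))

  expect_error(build_request(model, list(QUERY = "A")), class = "mb_argument_error")
  expect_error(build_request(model, list(QUERY = "A", JOB_TITLE = "t",
                                         DATABASE = "nr", BOGUS = "x")),
               class = "mb_argument_error")
})

test_that("request bodies are deterministic per seed and injective in values", {
  model <- blast_web_model(boundary_seed = 99L)
  vals <- list(QUERY = "AAAA", JOB_TITLE = "j", DATABASE = "nr")
  expect_identical(build_request(model, vals)$body, build_request(model, vals)$body)
  v2 <- vals
  v2$QUERY <- "CCCC"
  expect_false(identical(build_request(model, vals)$body,
                         build_request(model, v2)$body))

  bare <- web_api_model("/x", "GET", encoding = "urlencoded")
  req <- build_request(bare, list())
  expect_identical(req$url, "/x")
  expect_length(req$body, 0)
})

test_that("the configuration file dialect round-trips losslessly", {
  model <- blast_web_model()
  txt <- web_model_to_xml(model)
  reloaded <- web_model_from_xml(txt)
  expect_equal(reloaded, model)
})

test_that("tag paths parse, normalize, and reject malformed steps", {
  p <- tag_path("html[0]/Body[3]/td[1]")
  expect_identical(format(p), "HTML[0]/BODY[3]/TD[1]")
  expect_error(tag_path("HTML[0]/BODY[-1]"), class = "mb_path_error")
  expect_error(tag_path("HTML[0]//TD[1]"), class = "mb_path_error")
})

test_that("filters resolve planted values and miss loudly otherwise", {
  parsed <- parse_response_tags(blast_page_html())
  expect_identical(
    apply_filter(parsed, "HTML[0]/BODY[3]/DIV[1]/DIV[3]/DIV[7]/TABLE[7]/TR[1]/TD[1]"),
    "Z8PEFDYB016")
  expect_identical(apply_filter(parse_response_tags("<html>hi</html>"), "HTML[0]"),
                   "hi")
  simple <- parse_response_tags("<html><body>x</body></html>")
  expect_identical(apply_filter(simple, "HTML[0]/BODY[0]"), "x")
  err <- expect_error(apply_filter(simple, "HTML[0]/BODY[0]/DIV[4]"),
                      class = "mb_extraction_miss")
  expect_identical(err$step, 3L)
})

test_that("per-tag ordinal mode counts same-tag siblings only", {
  html <- "<html><body><p>a</p><div>b</div><div>c</div></body></html>"
  parsed <- parse_response_tags(html)
  expect_identical(apply_filter(parsed, "HTML[0]/BODY[0]/DIV[1]", "per-tag"), "c")
  expect_identical(apply_filter(parsed, "HTML[0]/BODY[0]/DIV[2]"), "c")
})

test_that("planted values are recoverable from random generated pages", {
  set.seed(421)
  for (i in 1:25) {
    value <- sprintf("PLANTED-%04d", sample.int(9999, 1))
    case <- random_planted_html(value)
    got <- apply_filter(parse_response_tags(case$html), case$path)
    expect_identical(got, value)
    # the path-finding helper agrees
    expect_true(case$path %in% find_tag_paths(case$html, value))
  }
})

test_that("end-to-end web invocation extracts configured filters", {
  html <- blast_page_html()
  transport <- function(req) list(status = 200L, body = html)
  out <- invoke_web_source(blast_web_model(),
                           list(QUERY = "ACGT", JOB_TITLE = "t", DATABASE = "nr"),
                           transport)
  expect_identical(out$values$job_id, "Z8PEFDYB016")
  expect_length(out$misses, 0)

  # empty page: recorded miss, no error
  out2 <- invoke_web_source(blast_web_model(),
                            list(QUERY = "A", JOB_TITLE = "t", DATABASE = "nr"),
                            function(req) list(status = 200L, body = "<html></html>"))
  expect_null(out2$values$job_id)
  expect_true("job_id" %in% names(out2$misses))

  # two filters, one present: one value plus one recorded miss
  m2 <- blast_web_model()
  m2$filters$second <- tag_path("HTML[0]/BODY[3]/TABLE[9]")
  out3 <- invoke_web_source(m2, list(QUERY = "A", JOB_TITLE = "t", DATABASE = "nr"),
                            transport)
  expect_identical(out3$values$job_id, "Z8PEFDYB016")
  expect_identical(names(out3$misses), "second")

  expect_error(invoke_web_source(blast_web_model(),
                                 list(QUERY = "A", JOB_TITLE = "t", DATABASE = "nr"),
                                 function(req) stop("connection refused")),
               class = "mb_transport_error")
})

test_that("web invocation works over a real local HTTP server", {
  port <- free_port()
  handle <- start_server_process(sprintf(
    "serve_http_blocking(function(req) list(status = 200L, body = blast_page_html(), content_type = 'text/html'), %d, max_requests = 5)",
    port), port)
  on.exit(stop_server(handle))
  out <- invoke_web_source(blast_web_model(),
                           list(QUERY = "ACGT", JOB_TITLE = "t", DATABASE = "nr"),
                           http_transport("127.0.0.1", port))
  expect_identical(out$values$job_id, "Z8PEFDYB016")
})
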