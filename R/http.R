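# Minimal HTTP/1.0 plumbing over base-R sockets: a blocking single-threaded
# server loop (for the optional service endpoint and for mock web sources)
# and a matching client transport. The wrapper layer constructs request
# bytes itself, so a raw socket transport keeps the path byte-faithful.

read_http_message <- function(con) {
  start <- readLines(con, n = 1)
  if (!length(start) || !nzchar(start)) return(NULL)
  headers <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !nzchar(line)) break
    idx <- regexpr(":", line, fixed = TRUE)
    if (idx > 0) {
      headers[[tolower(trimws(substr(line, 1, idx - 1)))]] <-
        trimws(substr(line, idx + 1, nchar(line)))
    }
  }
  clen <- as.integer(headers[["content-length"]] %||% "0")
  body <- raw(0)
  if (!is.na(clen) && clen > 0) {
    while (length(body) < clen) {
      chunk <- readBin(con, "raw", n = clen - length(body))
      if (!length(chunk)) break
      body <- c(body, chunk)
    }
  }
  list(start = start, headers = headers, body = body)
}

write_http_response <- function(con, status = 200L, body = "",
                                content_type = "application/json") {
  if (!is.raw(body)) body <- charToRaw(enc2utf8(paste0(body, collapse = "")))
  reason <- switch(as.character(status), "200" = "OK", "400" = "Bad Request",
                   "404" = "Not Found", "500" = "Internal Server Error", "OK")
  head <- paste0("HTTP/1.0 ", status, " ", reason, "\r\n",
                 "Content-Type: ", content_type, "\r\n",
                 "Content-Length: ", length(body), "\r\n",
                 "Connection: close\r\n\r\n")
  writeBin(c(charToRaw(head), body), con)
  flush(con)
}

#' Run a blocking HTTP server loop
#'
#' Single-threaded accept loop serving one request per connection. `handler`
#' receives `list(method, path, headers, body)` and returns `list(status,
#' body, content_type)`. Used by [serve_dcs()] and by the mock web sources;
#' normally run in a child process.
#'
#' @param handler Request handler function.
#' @param port TCP port to listen on.
#' @param max_requests Stop after this many requests (Inf to run forever).
#' @return Number of requests served, invisibly.
#' @export
serve_http_blocking <- function(handler, port, max_requests = Inf) {
  srv <- tryCatch(serverSocket(port), error = function(e) {
    mb_abort("mb_startup_error",
             sprintf("cannot bind port %d: %s", port, conditionMessage(e)))
  })
  on.exit(close(srv), add = TRUE)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "a+b")
    msg <- tryCatch(read_http_message(con), error = function(e) NULL)
    if (!is.null(msg)) {
      parts <- strsplit(msg$start, " ", fixed = TRUE)[[1]]
      req <- list(method = parts[1] %||% "GET", path = parts[2] %||% "/",
                  headers = msg$headers, body = msg$body)
      resp <- tryCatch(handler(req), error = function(e) {
        list(status = 500L, body = jsonlite::toJSON(
          list(error = conditionMessage(e)), auto_unbox = TRUE))
      })
      tryCatch(write_http_response(con, resp$status %||% 200L,
                                   resp$body %||% "",
                                   resp$content_type %||% "application/json"),
               error = function(e) NULL)
      served <- served + 1L   # liveness probes (empty connects) don't count
    }
    close(con)
  }
  invisible(served)
}

#' Send an HTTP request over a socket
#'
#' @param host,port Server address.
#' @param method,path,headers,body Request pieces; `body` may be raw or
#'   character. An `mb_http_request` from [build_request()] can be passed as
#'   `req` instead (its `url` is used as the path).
#' @param req Optional `mb_http_request`.
#' @param timeout Socket timeout in seconds.
#' @return `list(status, headers, body)` with `body` as text.
#' @export
http_send <- function(host, port, method = "GET", path = "/", headers = list(),
                      body = raw(0), req = NULL, timeout = 10) {
  if (!is.null(req)) {
    method <- req$method
    path <- req$url
    headers <- req$headers
    body <- req$body
  }
  if (!is.raw(body)) body <- charToRaw(enc2utf8(paste0(body, collapse = "")))
  if (!grepl("^/", path)) path <- sub("^https?://[^/]*", "", path)
  if (!nzchar(path)) path <- "/"
  if (is.null(headers[["Host"]])) headers[["Host"]] <- host
  if (length(body) && is.null(headers[["Content-Length"]])) {
    headers[["Content-Length"]] <- as.character(length(body))
  }
  head <- paste0(method, " ", path, " HTTP/1.0\r\n",
                 paste0(vapply(names(headers), function(h) {
                   paste0(h, ": ", headers[[h]], "\r\n")
                 }, ""), collapse = ""), "\r\n")
  con <- tryCatch(
    socketConnection(host, port, blocking = TRUE, open = "a+b", timeout = timeout),
    error = function(e) {
      mb_abort("mb_transport_error",
               sprintf("cannot connect to %s:%d: %s", host, port, conditionMessage(e)))
    })
  on.exit(close(con), add = TRUE)
  writeBin(c(charToRaw(head), body), con)
  flush(con)
  status_line <- readLines(con, n = 1)
  if (!length(status_line)) mb_abort("mb_transport_error", "empty HTTP response")
  status <- suppressWarnings(as.integer(strsplit(status_line, " ")[[1]][2]))
  resp_headers <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !nzchar(line)) break
    idx <- regexpr(":", line, fixed = TRUE)
    if (idx > 0) {
      resp_headers[[tolower(trimws(substr(line, 1, idx - 1)))]] <-
        trimws(substr(line, idx + 1, nchar(line)))
    }
  }
  clen <- as.integer(resp_headers[["content-length"]] %||% NA)
  rbody <- raw(0)
  if (!is.na(clen)) {
    while (length(rbody) < clen) {
      chunk <- readBin(con, "raw", n = clen - length(rbody))
      if (!length(chunk)) break
      rbody <- c(rbody, chunk)
    }
  } else {
    repeat {
      chunk <- readBin(con, "raw", n = 65536L)
      if (!length(chunk)) break
      rbody <- c(rbody, chunk)
    }
  }
  list(status = status, headers = resp_headers, body = rawToChar(rbody))
}

#' Socket transport for [invoke_web_source()]
#'
#' @param host,port Address of a local test server.
#' @return A transport function mapping an `mb_http_request` to the response.
#' @export
http_transport <- function(host, port) {
  force(host); force(port)
  function(req) http_send(host, port, req = req)
}

#' Start a server in a child R process
#'
#' Writes a small launcher script that loads the package, evaluates
#' `setup_code` (which must end in a blocking serve call), and runs it via
#' `Rscript`. Returns once the port accepts connections.
#'
#' @param setup_code R code as a string; evaluated in the child.
#' @param port Port the child is expected to listen on.
#' @param wait_s How long to wait for the port to come up.
#' @return A handle `list(port, pid_file, script)`; pass to [stop_server()].
#' @export
start_server_process <- function(setup_code, port, wait_s = 15) {
  script <- tempfile(fileext = ".R")
  pid_file <- tempfile(fileext = ".pid")
  writeLines(c(
    sprintf("writeLines(as.character(Sys.getpid()), %s)", deparse(pid_file)),
    "suppressPackageStartupMessages(library(metabind))",
    setup_code
  ), script)
  system2(file.path(R.home("bin"), "Rscript"), shQuote(script),
          stdout = FALSE, stderr = FALSE, wait = FALSE)
  deadline <- Sys.time() + wait_s
  repeat {
    ok <- tryCatch({
      con <- socketConnection("127.0.0.1", port, blocking = TRUE,
                              open = "a+b", timeout = 1)
      close(con)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) break
    if (Sys.time() > deadline) {
      mb_abort("mb_startup_error",
               sprintf("server on port %d did not come up within %ds", port, wait_s))
    }
    Sys.sleep(0.1)
  }
  list(port = port, pid_file = pid_file, script = script)
}

#' @rdname start_server_process
#' @param handle A handle from [start_server_process()].
#' @export
stop_server <- function(handle) {
  pid <- tryCatch(as.integer(readLines(handle$pid_file, warn = FALSE)[1]),
                  error = function(e) NA_integer_)
  if (!is.na(pid)) tools::pskill(pid)
  invisible(TRUE)
}

#' Pick a free local TCP port
#'
#' @param from,to Port range searched.
#' @return A port number.
#' @export
free_port <- function(from = 30000L, to = 50000L) {
  for (i in 1:50) {
    p <- sample.int(to - from, 1L) + from
    ok <- tryCatch({
      s <- serverSocket(p)
      close(s)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
  mb_abort("mb_startup_error", "no free port found")
}
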