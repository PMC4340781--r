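# Synthetic data and mock sources: everything the other modules need to be
# exercised offline, with machine-readable ground truth so round-trip tests
# are self-checking. All generators are pure functions of (seed, parameters).

# ---- GenBank-style record generation ---------------------------------------

gb_records <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    mb_bad_argument("`n` must be at least 1")
  }
  n <- as.integer(n)
  with_seed(seed, {
    lens <- sample(120:600, n, replace = TRUE)
    data.frame(
      accession = sprintf("SYN%06d", seq_len(n)),
      locus = sprintf("SYNGEN%03d", seq_len(n)),
      length = lens,
      origin = vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, ""),
      stringsAsFactors = FALSE
    )
  })
}

render_origin_lines <- function(sequence) {
  s <- tolower(sequence)
  L <- nchar(s)
  starts <- seq(1L, L, by = 60L)
  vapply(starts, function(st) {
    chunk <- substr(s, st, min(st + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), by = 10),
                        pmin(seq(10, nchar(chunk) + 9, by = 10), nchar(chunk)))
    sprintf("%9d %s", st, paste(groups, collapse = " "))
  }, "")
}

render_flat_record <- function(rec, i) {
  cds_end <- max(3L, rec$length - 30L)
  paste(c(
    sprintf("LOCUS       %-16s %6d bp    DNA     linear   SYN 01-JAN-2020",
            rec$locus, rec$length),
    sprintf("DEFINITION  Synthetic record %d for structured flat-file parsing.", i),
    sprintf("ACCESSION   %s", rec$accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length),
    "                     /organism=\"synthetic construct\"",
    sprintf("     gene            1..%d", rec$length),
    sprintf("     CDS             3..%d", cds_end),
    "ORIGIN",
    render_origin_lines(rec$origin),
    "//"
  ), collapse = "\n")
}

#' Generate GenBank-style flat-file records with ground truth
#'
#' Each record carries LOCUS/DEFINITION/ACCESSION header lines, a
#' `FEATURES             Location/Qualifiers` section with source/gene/CDS
#' stubs, and an ORIGIN section of numbered 60-residue lines terminated by
#' `//`. The ground-truth table records, per record, the accession, locus,
#' and origin sequence actually emitted. Deterministic per seed.
#'
#' @param n Number of records (>= 1).
#' @param seed RNG seed.
#' @return `list(text, truth)`: the flat-file text and the ground-truth
#'   data.frame (`accession`, `locus`, `length`, `origin`).
#' @export
generate_genbank_flat <- function(n, seed) {
  truth <- gb_records(n, seed)
  text <- paste(vapply(seq_len(nrow(truth)), function(i) {
    render_flat_record(truth[i, ], i)
  }, ""), collapse = "\n")
  list(text = paste0(text, "\n"), truth = truth)
}

#' Generate the XML rendering of the same records
#'
#' For a shared seed the flat-file and XML generators emit the same records,
#' so cross-wrapper extraction results can be compared directly.
#'
#' @param n Number of records (>= 1).
#' @param seed RNG seed.
#' @return `list(text, truth)`: XML text (`genbank_db` root, one
#'   `genbank_entry` per record) and the ground-truth data.frame.
#' @export
generate_genbank_xml <- function(n, seed) {
  truth <- gb_records(n, seed)
  entries <- vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    paste0('  <genbank_entry id="', r$accession, '">\n',
           "    <accession>", r$accession, "</accession>\n",
           "    <locus>", r$locus, "</locus>\n",
           "    <definition>Synthetic record ", i, "</definition>\n",
           "    <origin>", r$origin, "</origin>\n",
           "  </genbank_entry>")
  }, "")
  text <- paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
                 "<genbank_db>\n", paste(entries, collapse = "\n"),
                 "\n</genbank_db>\n")
  list(text = text, truth = truth)
}

#' Text schema for GenBank-style flat files
#'
#' A repeatable `genbank_entry` node starts at each line-initial `LOCUS`
#' token; within an entry, `HEAD` ends at the
#' `\nFEATURES\s+Location/Qualifiers` delimiter, `FEATURES` at `\nORIGIN`,
#' and `ORIGIN` at the `\n//` record terminator. The ORIGIN leaf's strip
#' rule removes position numbers and whitespace and uppercases the residue
#' letters.
#'
#' @return An `mb_text_schema`.
#' @export
genbank_text_schema <- function() {
  build_text_schema(list(
    name = "genbank-flat",
    tokens = c("LOCUS", "FEATURES", "ORIGIN"),
    root = list(
      node_name = "genbank_db",
      children = list(
        list(node_name = "genbank_entry",
             start_pattern = "(?m)^LOCUS",
             repeatable = TRUE,
             children = list(
               list(node_name = "HEAD",
                    end_pattern = "\\nFEATURES\\s+Location/Qualifiers",
                    strip_rule = "trim"),
               list(node_name = "FEATURES",
                    end_pattern = "\\nORIGIN",
                    strip_rule = "trim"),
               list(node_name = "ORIGIN",
                    end_pattern = "\\n//",
                    strip_rule = "origin_sequence")
             ))
      ))
  ))
}

#' DTD for the XML rendering of GenBank-style records
#'
#' @return DTD text matching [generate_genbank_xml()] documents.
#' @export
genbank_dtd <- function() {
  paste(
    "<!ELEMENT genbank_db (genbank_entry*)>",
    "<!ELEMENT genbank_entry (accession, locus, definition, origin)>",
    "<!ATTLIST genbank_entry id CDATA #IMPLIED>",
    "<!ELEMENT accession (#PCDATA)>",
    "<!ELEMENT locus (#PCDATA)>",
    "<!ELEMENT definition (#PCDATA)>",
    "<!ELEMENT origin (#PCDATA)>",
    sep = "\n")
}

# ---- BLAST-style web page fixture ------------------------------------------

#' Fixture HTML of a BLAST-style job-submission response
#'
#' The page is constructed so the job identifier sits exactly at the tag
#' path `HTML[0]/BODY[3]/DIV[1]/DIV[3]/DIV[7]/TABLE[7]/TR[1]/TD[1]` under
#' the element-ordinal convention (BODY is the fourth element child of HTML,
#' after HEAD, SCRIPT and STYLE).
#'
#' @param job_id Job identifier planted in the page.
#' @return HTML text.
#' @export
blast_page_html <- function(job_id = "Z8PEFDYB016") {
  pad <- function(tag, k) paste0(vapply(seq_len(k), function(i) {
    sprintf("<%s>filler %d</%s>", tag, i, tag)
  }, ""), collapse = "")
  paste0(
    "<html>",
    "<head><title>Job submitted</title></head>",
    "<script>var x = 1;</script>",
    "<style>.s { color: black }</style>",
    "<body>",
    "<h1>Sequence search</h1>",
    "<div>",                                   # BODY[1]
    pad("p", 3),
    "<div>",                                   # DIV[3]
    pad("span", 7),
    "<div>",                                   # DIV[7]
    pad("div", 7),
    "<table>",                                 # TABLE[7]
    "<tr><th>Field</th><th>Value</th></tr>",
    "<tr><td>Request ID</td><td>", job_id, "</td></tr>",
    "</table>",
    "</div></div></div>",
    "<p>Results will be available shortly.</p>",
    "</body></html>")
}

#' Web-API model of the BLAST-style submission endpoint
#'
#' POST multipart form with user parts QUERY, JOB_TITLE, DATABASE, fixed
#' parts QUERYFILE, db, BLAST_PROGRAMS, and one response filter (`job_id`)
#' at the fixture page's tag path.
#'
#' @param url Endpoint path or URL.
#' @param boundary_seed Seed for the multipart boundary generator.
#' @return An `mb_web_model`.
#' @export
blast_web_model <- function(url = "/blast/Put", boundary_seed = 20130204L) {
  web_api_model(
    url = url,
    http_method = "POST",
    request_headers = list(
      Accept = "text/html,application/xhtml+xml",
      Host = "localhost"),
    user_params = c("QUERY", "JOB_TITLE", "DATABASE"),
    default_params = list(QUERYFILE = "", db = "core", BLAST_PROGRAMS = "blastn"),
    encoding = "multipart-form",
    boundary_seed = boundary_seed,
    filters = list(job_id = "HTML[0]/BODY[3]/DIV[1]/DIV[3]/DIV[7]/TABLE[7]/TR[1]/TD[1]"))
}

# ---- null-method suite ------------------------------------------------------

#' Null-method suite for overhead measurement
#'
#' Callables `m0()` .. `m3(p1, p2, p3)` with distinct declared parameter
#' types (`T1`, `T2`, `T3`), side-effect free except for per-method call
#' counters.
#'
#' @return A list with the suite environment (`env`), the callables exposed
#'   as a component object (`object`), and per-method
#'   [callable_descriptor()]s (`descriptors`).
#' @export
make_null_suite <- function() {
  env <- new.env(parent = emptyenv())
  env$calls <- c(m0 = 0L, m1 = 0L, m2 = 0L, m3 = 0L)
  object <- list(
    m0 = function() { env$calls[["m0"]] <- env$calls[["m0"]] + 1L; invisible(NULL) },
    m1 = function(p1) { env$calls[["m1"]] <- env$calls[["m1"]] + 1L; invisible(NULL) },
    m2 = function(p1, p2) { env$calls[["m2"]] <- env$calls[["m2"]] + 1L; invisible(NULL) },
    m3 = function(p1, p2, p3) { env$calls[["m3"]] <- env$calls[["m3"]] + 1L; invisible(NULL) }
  )
  types <- list(character(), "T1", c("T1", "T2"), c("T1", "T2", "T3"))
  descriptors <- lapply(0:3, function(k) {
    specs <- if (k == 0) list() else lapply(seq_len(k), function(j) {
      list(name = paste0("p", j), type = types[[k + 1]][j])
    })
    callable_descriptor("null.suite", paste0("m", k), specs, return_type = "any")
  })
  names(descriptors) <- paste0("m", 0:3)
  list(env = env, object = object, descriptors = descriptors)
}

# ---- mock source set --------------------------------------------------------

.mb_counter <- new.env(parent = emptyenv())
.mb_counter$n <- 0L

next_instance_id <- function(prefix) {
  .mb_counter$n <- .mb_counter$n + 1L
  sprintf("%s-%d", prefix, .mb_counter$n)
}

#' Expected mock protein record for a query
#'
#' @param mocks A mock set from [make_mock_sources()].
#' @param query,db,format The call arguments.
#' @return The record text `fetchData` returns for these arguments.
#' @export
mock_protein_record <- function(mocks, query, db = "pdb", format = "raw") {
  sprintf("%s|query=%s|db=%s|format=%s", mocks$ebi$payload, query, db, format)
}

#' Swap the payload behind the mock protein service
#'
#' Mutates the live service module without touching the registry or any
#' mapping — the hot-swap path: the next call through the unchanged
#' ontology metadata returns records built from the new payload.
#'
#' @param mocks A mock set.
#' @param payload New payload stamp.
#' @return The mock set, invisibly.
#' @export
mock_set_protein_payload <- function(mocks, payload) {
  mocks$ebi$payload <- payload
  invisible(mocks)
}

#' Build the full mock source set
#'
#' Registers, in a fresh ontology registry: a web-service source (`EBI`)
#' whose complex `FetchData` operation runs the three-action state machine
#' `FetchData.xml`; an in-memory FTP-like source (`FTP-mock`) with `File`
#' and `Directory` elements and five simple operations; an embedded
#' relational source (`GeneDB`) with a seeded `bio_gene_db` table; and a
#' web-page source (`BLAST`) whose response HTML carries a job id at the
#' configured tag path.
#'
#' @param seed Seed controlling all generated content.
#' @param n_genes Rows seeded into `bio_gene_db`.
#' @param blast_transport `"inprocess"` (a transport function returning the
#'   fixture page) or `"http"` (start a local child-process server).
#' @return A list of class `mb_mockset`: `service`, `registry`,
#'   `components`, `ebi` (live module), `ftp` (filesystem env), `db`
#'   (connection), `genes` (seeded rows), `blast` (`html`, `model`,
#'   `transport`, maybe `server`).
#' @export
make_mock_sources <- function(seed = 1, n_genes = 20,
                              blast_transport = c("inprocess", "http")) {
  blast_transport <- match.arg(blast_transport)
  registry <- new_registry()
  components <- new_component_registry()

  # --- EBI web service -------------------------------------------------------
  ebi <- new.env(parent = emptyenv())
  ebi$payload <- sprintf("MOCK-PROTEIN[seed=%d]", as.integer(seed))
  ebi_module <- list(
    init = function() "ebi-session",
    create = function() {
      list(fetchData = function(query, db, format) {
        sprintf("%s|query=%s|db=%s|format=%s", ebi$payload, query, db, format)
      })
    })
  register_component(components, "EBI.module", ebi_module)

  fetch_model <- build_linear_model(
    list(list(op = "webserviceInitialization", result_key = "object0"),
         list(op = "webserviceConstructor", result_key = "object1"),
         list(op = "Access-Read", result_key = "fetchResult")),
    model_id = "FetchData.xml")

  register_source(
    registry,
    data_source_entry("EBI", "web_service",
                      "Mock protein-data web service"),
    elements = list(
      data_element("Protein",
                   attributes = list(list(name = "ProteinID", type = "string"),
                                     list(name = "query", type = "string"),
                                     list(name = "db", type = "string"),
                                     list(name = "format", type = "string")),
                   user_operations = "FetchData",
                   ui_hint = list(component = "imp.ui.StringInput",
                                  method = "getValue"))),
    mappings = list(
      api_mapping("webserviceInitialization", "EBI",
                  callable_descriptor("EBI.module", "init"),
                  result_key = "object0", result_type = "session",
                  aliases = "Initialize"),
      api_mapping("webserviceConstructor", "EBI",
                  callable_descriptor("EBI.module", "create"),
                  result_key = "object1", result_type = "service_object",
                  register_result_as = "object1", aliases = "Create"),
      api_mapping("Access-read", "EBI",
                  callable_descriptor("object1", "fetchData",
                                      parameter_specs = c("query", "db", "format"),
                                      return_type = "ProteinRecord"),
                  result_key = "fetchResult", result_type = "ProteinRecord",
                  aliases = "Access-Read")),
    operations = list(
      user_operation("FetchData", "EBI", "Protein", "complex", "FetchData.xml")),
    models = list("FetchData.xml" = fetch_model$text))

  # --- FTP-like source -------------------------------------------------------
  ftp <- new.env(parent = emptyenv())
  ftp$files <- list("/a.txt" = "alpha file contents",
                    "/data/b.txt" = "beta file contents")
  ftp$cwd <- "/"
  ftp_module <- list(
    read = function(path) {
      f <- ftp$files[[path]]
      if (is.null(f)) stop(sprintf("no such file: %s", path))
      f
    },
    write = function(path, content) {
      ftp$files[[path]] <- content
      path
    },
    delete = function(path) {
      if (is.null(ftp$files[[path]])) stop(sprintf("no such file: %s", path))
      ftp$files[[path]] <- NULL
      path
    },
    up = function() {
      ftp$cwd <- sub("[^/]+/?$", "", ftp$cwd)
      if (!nzchar(ftp$cwd)) ftp$cwd <- "/"
      ftp$cwd
    },
    down = function(name) {
      ftp$cwd <- paste0(sub("/?$", "/", ftp$cwd), name, "/")
      ftp$cwd
    })
  register_component(components, "FTP.module", ftp_module)

  ftp_attrs <- c("name", "size", "date", "type", "userID", "groupID",
                 "permissions", "numberofLinks")
  register_source(
    registry,
    data_source_entry("FTP-mock", "ftp", "In-memory FTP-like source"),
    elements = list(
      data_element("File", attributes = ftp_attrs,
                   user_operations = c("Read", "Write", "Delete")),
      data_element("Directory", attributes = ftp_attrs,
                   user_operations = c("Up_Navigation", "Down_Navigation"))),
    mappings = list(
      api_mapping("ftp.read", "FTP-mock",
                  callable_descriptor("FTP.module", "read", c("path")),
                  result_key = "fileContent", result_type = "FileContent"),
      api_mapping("ftp.write", "FTP-mock",
                  callable_descriptor("FTP.module", "write", c("path", "content")),
                  result_key = "writtenPath"),
      api_mapping("ftp.delete", "FTP-mock",
                  callable_descriptor("FTP.module", "delete", c("path")),
                  result_key = "deletedPath"),
      api_mapping("ftp.up", "FTP-mock",
                  callable_descriptor("FTP.module", "up"),
                  result_key = "cwd"),
      api_mapping("ftp.down", "FTP-mock",
                  callable_descriptor("FTP.module", "down", c("name")),
                  result_key = "cwd")),
    operations = list(
      user_operation("Read", "FTP-mock", "File", "simple", "ftp.read"),
      user_operation("Write", "FTP-mock", "File", "simple", "ftp.write"),
      user_operation("Delete", "FTP-mock", "File", "simple", "ftp.delete"),
      user_operation("Up_Navigation", "FTP-mock", "Directory", "simple", "ftp.up"),
      user_operation("Down_Navigation", "FTP-mock", "Directory", "simple", "ftp.down")))

  # --- embedded relational source -------------------------------------------
  db_id <- next_instance_id(sprintf("GeneDB-%d", as.integer(seed)))
  con <- db_connect(list(engine = "embedded", id = db_id))
  db_create_table(con, "bio_gene_db", list(
    list(name = "gene_id", type = "TEXT", nullable = FALSE, pk = TRUE),
    list(name = "locus", type = "TEXT"),
    list(name = "origin", type = "TEXT")))
  genes <- gb_records(n_genes, seed)
  genes$gene_id <- sprintf("g%d", seq_len(nrow(genes)))
  schema <- read_db_schema(con)
  for (i in seq_len(nrow(genes))) {
    ins <- build_statement(sql_statement("Insert", "bio_gene_db",
                                         assignments = list(gene_id = genes$gene_id[i],
                                                            locus = genes$locus[i],
                                                            origin = genes$origin[i])),
                           schema)
    execute_statement(con, ins$sql, ins$params)
  }
  gene_classification <- list(
    Gene = list(table = "bio_gene_db", key_columns = "gene_id",
                columns = c("gene_id", "locus", "origin")))
  db_adapter <- list(
    fetchOrigin = function(gene_id) {
      stmt <- select_pattern("FetchData", "Gene", list(gene_id = gene_id),
                             gene_classification)
      built <- build_statement(stmt, read_db_schema(con))
      rows <- execute_statement(con, built$sql, built$params)
      if (!nrow(rows)) stop(sprintf("no gene with id '%s'", gene_id))
      rows$origin[[1]]
    })
  register_component(components, "GeneDB.adapter", db_adapter)
  register_source(
    registry,
    data_source_entry("GeneDB", "relational_database",
                      "Embedded gene database",
                      connection_config = list(engine = "embedded", id = db_id)),
    elements = list(
      data_element("Gene", attributes = c("gene_id", "locus", "origin"),
                   user_operations = "FetchData")),
    mappings = list(
      api_mapping("Access-read", "GeneDB",
                  callable_descriptor("GeneDB.adapter", "fetchOrigin", c("gene_id"),
                                      return_type = "DNA"),
                  result_key = "origin", result_type = "DNA")),
    operations = list(
      user_operation("FetchData", "GeneDB", "Gene", "simple", "Access-read")))

  # --- BLAST-like web page source -------------------------------------------
  html <- blast_page_html()
  model <- blast_web_model()
  blast <- list(html = html, model = model)
  if (blast_transport == "inprocess") {
    blast$transport <- function(req) list(status = 200L, headers = list(), body = html)
  } else {
    port <- free_port()
    blast$server <- start_server_process(sprintf(
      "serve_http_blocking(function(req) list(status = 200L, body = blast_page_html(), content_type = 'text/html'), %d, max_requests = 1000)",
      port), port)
    blast$transport <- http_transport("127.0.0.1", port)
  }
  blast_adapter <- list(
    submit = function(QUERY, JOB_TITLE, DATABASE) {
      out <- invoke_web_source(model,
                               list(QUERY = QUERY, JOB_TITLE = JOB_TITLE,
                                    DATABASE = DATABASE),
                               blast$transport)
      if (is.null(out$values$job_id)) {
        mb_abort("mb_extraction_miss",
                 paste("job_id filter missed:", out$misses$job_id %||% "unknown"))
      }
      out$values$job_id
    })
  register_component(components, "BLAST.adapter", blast_adapter)
  register_source(
    registry,
    data_source_entry("BLAST", "web_page", "Mock sequence-search submission page"),
    elements = list(
      data_element("BlastJob", attributes = c("QUERY", "JOB_TITLE", "DATABASE"),
                   user_operations = "SubmitQuery")),
    mappings = list(
      api_mapping("web.submit", "BLAST",
                  callable_descriptor("BLAST.adapter", "submit",
                                      c("QUERY", "JOB_TITLE", "DATABASE")),
                  result_key = "job_id", result_type = "JobID")),
    operations = list(
      user_operation("SubmitQuery", "BLAST", "BlastJob", "simple", "web.submit")))

  service <- dcs_service(registry, components)
  structure(list(service = service, registry = registry,
                 components = components, ebi = ebi, ftp = ftp,
                 db = con, genes = genes, blast = blast,
                 seed = seed),
            class = "mb_mockset")
}
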