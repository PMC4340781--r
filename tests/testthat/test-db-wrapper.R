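fresh_db <- local({
  k <- 0L
  function() {
    k <<- k + 1L
    con <- db_connect(list(engine = "embedded", id = sprintf("test-db-%d-%d", Sys.getpid(), k)))
    db_create_table(con, "bio_gene_db", list(
      list(name = "gene_id", nullable = FALSE, pk = TRUE),
      list(name = "locus"),
      list(name = "origin")))
    con
  }
})

gene_cls <- list(Gene = list(table = "bio_gene_db", key_columns = "gene_id",
                             columns = c("gene_id", "locus", "origin")))

test_that("schema reading lists all user tables and columns", {
  con <- fresh_db()
  model <- read_db_schema(con)
  expect_identical(vapply(model$tables, `[[`, "", "name"), "bio_gene_db")
  expect_identical(model$tables[[1]]$columns$name, c("gene_id", "locus", "origin"))
  # agrees with direct catalog introspection of the store
  expect_identical(model$tables[[1]]$columns,
                   con$db$tables[["bio_gene_db"]]$columns)
  empty <- db_connect(list(engine = "embedded", id = paste0("empty-", Sys.getpid())))
  expect_length(read_db_schema(empty)$tables, 0)
  expect_error(db_connect(list(engine = "oracle-11g")), class = "mb_connection_error")
})

test_that("statement building is parameterized, validated, and deterministic", {
  schema <- read_db_schema(fresh_db())
  sel <- build_statement(sql_statement("Select", "bio_gene_db",
                                       select_columns = "origin",
                                       predicates = list(list(column = "gene_id",
                                                              op = "=", value = "g1"))),
                         schema)
  expect_identical(sel$sql, "SELECT origin FROM bio_gene_db WHERE gene_id = ?")
  expect_identical(sel$params, list("g1"))

  ins <- build_statement(sql_statement("Insert", "bio_gene_db",
                                       assignments = list(gene_id = "g1", locus = "L",
                                                          origin = "ACGT")),
                         schema)
  expect_identical(lengths(regmatches(ins$sql, gregexpr("?", ins$sql, fixed = TRUE))),
                   3L)

  expect_error(build_statement(sql_statement("Delete", "bio_gene_db"), schema),
               class = "mb_validation_error")
  expect_error(build_statement(sql_statement("Select", "no_such_table",
                                             select_columns = "x"), schema),
               class = "mb_validation_error")
  expect_error(build_statement(sql_statement("Select", "bio_gene_db",
                                             select_columns = "no_such_col"), schema),
               class = "mb_validation_error")
})

test_that("emitted SQL never interpolates parameter values", {
  schema <- read_db_schema(fresh_db())
  nasty <- "x'; DROP TABLE bio_gene_db; --"
  for (stmt in list(
    sql_statement("Select", "bio_gene_db", select_columns = "origin",
                  predicates = list(list(column = "gene_id", op = "=", value = nasty))),
    sql_statement("Insert", "bio_gene_db", assignments = list(gene_id = nasty)),
    sql_statement("Update", "bio_gene_db", assignments = list(locus = nasty),
                  predicates = list(list(column = "gene_id", op = "=", value = nasty))),
    sql_statement("Delete", "bio_gene_db",
                  predicates = list(list(column = "gene_id", op = "LIKE", value = nasty))))) {
    built <- build_statement(stmt, schema)
    expect_false(grepl(nasty, built$sql, fixed = TRUE))
    expect_true(nasty %in% unlist(built$params))
  }
})

test_that("insert/select round trips recover values for random rows", {
  con <- fresh_db()
  schema <- read_db_schema(con)
  set.seed(17)
  rows <- data.frame(
    gene_id = sprintf("g%03d", sample(1000, 50)),
    locus = replicate(50, paste(sample(LETTERS, 8), collapse = "")),
    origin = replicate(50, paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                                 collapse = "")),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rows))) {
    ins <- build_statement(sql_statement("Insert", "bio_gene_db",
                                         assignments = as.list(rows[i, ])), schema)
    expect_identical(execute_statement(con, ins$sql, ins$params), 1L)
  }
  for (i in seq_len(nrow(rows))) {
    sel <- build_statement(sql_statement("Select", "bio_gene_db",
                                         select_columns = c("locus", "origin"),
                                         predicates = list(list(column = "gene_id",
                                                                op = "=",
                                                                value = rows$gene_id[i]))),
                           schema)
    got <- execute_statement(con, sel$sql, sel$params)
    # independent oracle: direct lookup in the backing store
    direct <- con$db$tables[["bio_gene_db"]]$rows
    direct <- direct[direct$gene_id == rows$gene_id[i], c("locus", "origin")]
    expect_identical(unname(unlist(got)), unname(unlist(direct)))
    expect_identical(got$origin, rows$origin[i])
  }
  empty_sel <- build_statement(sql_statement("Select", "bio_gene_db",
                                             select_columns = "origin",
                                             predicates = list(list(column = "gene_id",
                                                                    op = "=",
                                                                    value = "absent"))),
                               schema)
  expect_identical(nrow(execute_statement(con, empty_sel$sql, empty_sel$params)), 0L)
})

test_that("update, delete, LIKE and constraint errors behave", {
  con <- fresh_db()
  schema <- read_db_schema(con)
  ins <- function(id, locus) {
    s <- build_statement(sql_statement("Insert", "bio_gene_db",
                                       assignments = list(gene_id = id, locus = locus,
                                                          origin = "ACGT")), schema)
    execute_statement(con, s$sql, s$params)
  }
  ins("g1", "alpha")
  ins("g2", "beta")
  expect_error(ins("g1", "dup"), class = "mb_sql_error")

  upd <- build_statement(sql_statement("Update", "bio_gene_db",
                                       assignments = list(locus = "gamma"),
                                       predicates = list(list(column = "gene_id",
                                                              op = "=", value = "g2"))),
                         schema)
  expect_identical(execute_statement(con, upd$sql, upd$params), 1L)

  like <- build_statement(sql_statement("Select", "bio_gene_db",
                                        select_columns = "gene_id",
                                        predicates = list(list(column = "locus",
                                                               op = "LIKE",
                                                               value = "ga%"))),
                          schema)
  expect_identical(execute_statement(con, like$sql, like$params)$gene_id, "g2")

  del <- build_statement(sql_statement("Delete", "bio_gene_db",
                                       predicates = list(list(column = "gene_id",
                                                              op = "=", value = "g1"))),
                         schema)
  expect_identical(execute_statement(con, del$sql, del$params), 1L)
  expect_identical(nrow(con$db$tables[["bio_gene_db"]]$rows), 1L)
})

test_that("pattern selection maps operations to valid statement models", {
  schema <- read_db_schema(fresh_db())
  sel <- select_pattern("FetchData", "Gene", list(gene_id = "g1"), gene_cls)
  expect_identical(sel$kind, "Select")
  expect_identical(sel$predicates[[1]]$column, "gene_id")
  expect_error(select_pattern("Delete", "Gene", list(), gene_cls),
               class = "mb_pattern_error")

  set.seed(5)
  for (i in 1:20) {
    op <- sample(c("FetchData", "Write", "Delete"), 1)
    inputs <- list(gene_id = sprintf("g%d", i))
    if (op == "Write") {
      if (runif(1) < 0.5) {
        inputs$locus <- "L"
        inputs$origin <- "ACGT"
      } else {
        inputs$locus <- "L2"
      }
    }
    stmt <- select_pattern(op, "Gene", inputs, gene_cls)
    expect_silent(build_statement(stmt, schema))
  }
})

test_that("ontology-routed fetches equal hand-written queries", {
  mocks <- make_mock_sources(seed = 8, n_genes = 25)
  schema <- read_db_schema(mocks$db)
  set.seed(8)
  for (id in sample(mocks$genes$gene_id, 20)) {
    routed <- ds_operation(mocks$service, "FetchData", "GeneDB", "Gene",
                           parameters = list(gene_id = id))$payload
    manual <- build_statement(sql_statement("Select", "bio_gene_db",
                                            select_columns = "origin",
                                            predicates = list(list(column = "gene_id",
                                                                   op = "=", value = id))),
                              schema)
    expect_identical(routed,
                     execute_statement(mocks$db, manual$sql, manual$params)$origin)
  }
})
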