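# Generic relational database wrapper: read a schema into classifiable
# metadata, build parameterized SQL from a statement model, and execute it.
#
# Statements are always parameterized ('?' placeholders, values passed
# separately); values are never interpolated into SQL text. Execution runs
# against a small embedded, in-memory table store that accepts exactly the
# single-table SQL subset the builder emits (Select/Insert/Update/Delete,
# conjunctive predicates with =, <, >, LIKE).

.db_pool <- new.env(parent = emptyenv())

#' Connect to an embedded database
#'
#' @param connection_config A list with `engine = "embedded"` and `id`
#'   (databases with the same id share state within the R session).
#' @return A connection of class `mb_db`.
#' @export
db_connect <- function(connection_config) {
  if (!identical(connection_config$engine, "embedded")) {
    mb_abort("mb_connection_error",
             sprintf("cannot reach database engine '%s'",
                     connection_config$engine %||% "<missing>"))
  }
  id <- connection_config$id %||% "default"
  if (is.null(.db_pool[[id]])) {
    db <- new.env(parent = emptyenv())
    db$tables <- list()    # name -> list(columns = data.frame, rows = data.frame)
    .db_pool[[id]] <- db
  }
  structure(list(id = id, db = .db_pool[[id]]), class = "mb_db")
}

#' Create (or replace) a table in an embedded database
#'
#' @param con An [db_connect()] connection.
#' @param name Table name.
#' @param columns List of column descriptors `list(name, type, nullable, pk)`
#'   (defaults: `type = "TEXT"`, `nullable = TRUE`, `pk = FALSE`).
#' @return The connection, invisibly.
#' @export
db_create_table <- function(con, name, columns) {
  stopifnot(inherits(con, "mb_db"))
  cols <- lapply(columns, function(cl) {
    if (is_string(cl)) cl <- list(name = cl)
    list(name = cl$name, type = cl$type %||% "TEXT",
         nullable = cl$nullable %||% TRUE, pk = isTRUE(cl$pk))
  })
  cn <- vapply(cols, `[[`, "", "name")
  if (anyDuplicated(cn)) mb_invalid(sprintf("duplicate column names in table '%s'", name))
  empty <- as.data.frame(stats::setNames(rep(list(character()), length(cn)), cn),
                         stringsAsFactors = FALSE)
  con$db$tables[[name]] <- list(
    columns = data.frame(name = cn,
                         type = vapply(cols, `[[`, "", "type"),
                         nullable = vapply(cols, `[[`, TRUE, "nullable"),
                         pk = vapply(cols, `[[`, FALSE, "pk"),
                         stringsAsFactors = FALSE),
    rows = empty)
  invisible(con)
}

#' Read a database schema into a classifiable model
#'
#' @param connection_config Connection configuration (see [db_connect()]),
#'   or an existing `mb_db` connection.
#' @return An object of class `mb_db_schema`: `tables` is a list of
#'   `list(name, columns)` with ordered column descriptors.
#' @export
read_db_schema <- function(connection_config) {
  con <- if (inherits(connection_config, "mb_db")) connection_config
         else db_connect(connection_config)
  tables <- lapply(names(con$db$tables), function(nm) {
    list(name = nm, columns = con$db$tables[[nm]]$columns)
  })
  structure(list(tables = tables), class = "mb_db_schema")
}

SQL_KINDS <- c("Select", "Insert", "Update", "Delete")
SQL_OPS <- c("=", "<", ">", "LIKE")

#' Model a SQL statement
#'
#' @param kind `"Select"`, `"Insert"`, `"Update"` or `"Delete"`.
#' @param table Target table.
#' @param select_columns Ordered columns for Select.
#' @param assignments Named list column -> value for Insert/Update.
#' @param predicates List of `list(column, op, value)` conjuncts; `op` one of
#'   `=`, `<`, `>`, `LIKE`.
#' @param allow_full_table Set `TRUE` to permit an Update/Delete with no
#'   predicate (off by default as a safety measure).
#' @return An object of class `mb_sql_stmt`.
#' @export
sql_statement <- function(kind, table, select_columns = character(),
                          assignments = list(), predicates = list(),
                          allow_full_table = FALSE) {
  if (!kind %in% SQL_KINDS) {
    mb_invalid(sprintf("unknown statement kind '%s'", kind))
  }
  predicates <- lapply(predicates, function(p) {
    if (!p$op %in% SQL_OPS) mb_invalid(sprintf("unsupported predicate operator '%s'", p$op))
    list(column = p$column, op = p$op, value = p$value)
  })
  structure(list(kind = kind, table = table,
                 select_columns = as.character(select_columns),
                 assignments = assignments, predicates = predicates,
                 allow_full_table = isTRUE(allow_full_table)),
            class = "mb_sql_stmt")
}

sql_ident <- function(x) {
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)) x
  else paste0('"', gsub('"', '""', x), '"')
}

#' Build parameterized SQL text from a statement model
#'
#' Validates the model against the schema and deparses it into SQL with `?`
#' placeholders plus the ordered parameter values. No value ever appears in
#' the SQL text.
#'
#' @param stmt An [sql_statement()].
#' @param schema An `mb_db_schema` from [read_db_schema()].
#' @return A list `(sql, params)`.
#' @export
build_statement <- function(stmt, schema) {
  stopifnot(inherits(stmt, "mb_sql_stmt"), inherits(schema, "mb_db_schema"))
  tnames <- vapply(schema$tables, `[[`, "", "name")
  ti <- match(stmt$table, tnames)
  if (is.na(ti)) mb_invalid(sprintf("unknown table '%s'", stmt$table))
  cols <- schema$tables[[ti]]$columns$name
  check_cols <- function(cs, what) {
    bad <- setdiff(cs, cols)
    if (length(bad)) {
      mb_invalid(sprintf("unknown column(s) in %s of '%s': %s", what, stmt$table,
                         paste(bad, collapse = ", ")))
    }
  }
  check_cols(stmt$select_columns, "select list")
  check_cols(names(stmt$assignments), "assignments")
  check_cols(vapply(stmt$predicates, `[[`, "", "column"), "predicates")

  where <- function() {
    if (!length(stmt$predicates)) return(list(sql = "", params = list()))
    conj <- vapply(stmt$predicates, function(p) {
      paste0(sql_ident(p$column), " ", p$op, " ?")
    }, "")
    list(sql = paste0(" WHERE ", paste(conj, collapse = " AND ")),
         params = lapply(stmt$predicates, `[[`, "value"))
  }

  switch(stmt$kind,
    Select = {
      if (!length(stmt$select_columns)) mb_invalid("Select requires select_columns")
      if (length(stmt$assignments)) mb_invalid("Select takes no assignments")
      w <- where()
      list(sql = paste0("SELECT ", paste(vapply(stmt$select_columns, sql_ident, ""),
                                         collapse = ", "),
                        " FROM ", sql_ident(stmt$table), w$sql),
           params = w$params)
    },
    Insert = {
      if (!length(stmt$assignments)) mb_invalid("Insert requires assignments")
      if (length(stmt$predicates)) mb_invalid("Insert takes no predicates")
      ks <- names(stmt$assignments)
      list(sql = paste0("INSERT INTO ", sql_ident(stmt$table), " (",
                        paste(vapply(ks, sql_ident, ""), collapse = ", "),
                        ") VALUES (", paste(rep("?", length(ks)), collapse = ", "), ")"),
           params = unname(stmt$assignments))
    },
    Update = {
      if (!length(stmt$assignments)) mb_invalid("Update requires assignments")
      if (!length(stmt$predicates) && !stmt$allow_full_table) {
        mb_invalid("Update without predicates requires allow_full_table = TRUE")
      }
      w <- where()
      ks <- names(stmt$assignments)
      list(sql = paste0("UPDATE ", sql_ident(stmt$table), " SET ",
                        paste(vapply(ks, function(k) paste0(sql_ident(k), " = ?"), ""),
                              collapse = ", "), w$sql),
           params = c(unname(stmt$assignments), w$params))
    },
    Delete = {
      if (length(stmt$assignments)) mb_invalid("Delete takes no assignments")
      if (!length(stmt$predicates) && !stmt$allow_full_table) {
        mb_invalid("Delete without predicates requires allow_full_table = TRUE")
      }
      w <- where()
      list(sql = paste0("DELETE FROM ", sql_ident(stmt$table), w$sql),
           params = w$params)
    })
}

# ---- execution (embedded engine) -------------------------------------------

strip_quotes <- function(x) gsub('^"|"$', "", x)

parse_where <- function(clause) {
  if (!nzchar(clause)) return(list())
  conj <- strsplit(clause, " AND ", fixed = TRUE)[[1]]
  lapply(conj, function(c1) {
    m <- regmatches(c1, regexec('^\\s*("?[A-Za-z_][A-Za-z0-9_]*"?)\\s+(=|<|>|LIKE)\\s+\\?\\s*$',
                                c1, perl = TRUE))[[1]]
    if (length(m) != 3L) mb_parse_failure(sprintf("cannot parse predicate '%s'", c1))
    list(column = strip_quotes(m[2]), op = m[3])
  })
}

match_rows <- function(rows, preds, params, from) {
  keep <- rep(TRUE, nrow(rows))
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    v <- params[[from + i - 1L]]
    col <- rows[[p$column]]
    keep <- keep & switch(p$op,
      "=" = col == as.character(v),
      "<" = col < as.character(v),
      ">" = col > as.character(v),
      "LIKE" = {
        esc <- gsub("([^[:alnum:]%])", "\\\\\\1", as.character(v))
        grepl(paste0("^", gsub("%", ".*", esc), "$"), col, perl = TRUE)
      })
  }
  keep
}

#' Execute a built statement against an embedded database
#'
#' Select returns the matching rows (as a data.frame in table order, selected
#' columns only); Insert/Update/Delete return the affected-row count. Each
#' call is one implicit transaction: on error the table is left untouched.
#'
#' @param con An [db_connect()] connection (or a connection_config list).
#' @param sql SQL text from [build_statement()].
#' @param params Ordered parameter values.
#' @return A data.frame (Select) or an integer count.
#' @export
execute_statement <- function(con, sql, params = list()) {
  if (!inherits(con, "mb_db")) con <- db_connect(con)
  n_ph <- lengths(regmatches(sql, gregexpr("?", sql, fixed = TRUE)))
  if (n_ph != length(params)) {
    mb_invalid(sprintf("statement has %d placeholder(s) but %d parameter(s) given [%s]",
                       n_ph, length(params), sql))
  }
  fail <- function(msg) mb_abort("mb_sql_error", sprintf("%s [%s]", msg, sql))
  get_table <- function(nm) {
    t <- con$db$tables[[strip_quotes(nm)]]
    if (is.null(t)) fail(sprintf("no such table '%s'", nm))
    t
  }

  if (grepl("^SELECT ", sql)) {
    m <- regmatches(sql, regexec("^SELECT (.*) FROM (\\S+)( WHERE (.*))?$", sql))[[1]]
    if (length(m) < 3L) fail("cannot parse SELECT")
    cols <- strip_quotes(trimws(strsplit(m[2], ",", fixed = TRUE)[[1]]))
    t <- get_table(m[3])
    preds <- parse_where(if (length(m) >= 5L) m[5] else "")
    keep <- match_rows(t$rows, preds, params, 1L)
    t$rows[keep, cols, drop = FALSE]
  } else if (grepl("^INSERT INTO ", sql)) {
    m <- regmatches(sql, regexec("^INSERT INTO (\\S+) \\((.*)\\) VALUES \\((.*)\\)$", sql))[[1]]
    if (length(m) != 4L) fail("cannot parse INSERT")
    tname <- strip_quotes(m[2])
    t <- get_table(m[2])
    cols <- strip_quotes(trimws(strsplit(m[3], ",", fixed = TRUE)[[1]]))
    row <- t$rows[0, , drop = FALSE][1, , drop = FALSE]
    row[1, ] <- NA_character_
    for (i in seq_along(cols)) row[1, cols[i]] <- as.character(params[[i]])
    spec <- t$columns
    pk <- spec$name[spec$pk]
    for (k in pk) {
      if (row[1, k] %in% t$rows[[k]]) {
        fail(sprintf("primary-key constraint violated on '%s.%s'", tname, k))
      }
    }
    not_null <- spec$name[!spec$nullable]
    if (any(is.na(row[1, not_null]))) {
      fail(sprintf("NOT NULL constraint violated on '%s'", tname))
    }
    con$db$tables[[tname]]$rows <- rbind(t$rows, row)
    1L
  } else if (grepl("^UPDATE ", sql)) {
    m <- regmatches(sql, regexec("^UPDATE (\\S+) SET (.*?)( WHERE (.*))?$", sql))[[1]]
    if (length(m) < 3L) fail("cannot parse UPDATE")
    tname <- strip_quotes(m[2])
    t <- get_table(m[2])
    sets <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    set_cols <- vapply(sets, function(s) {
      strip_quotes(trimws(sub("\\s*=\\s*\\?$", "", s)))
    }, "")
    preds <- parse_where(if (length(m) >= 5L) m[5] else "")
    keep <- match_rows(t$rows, preds, params, length(set_cols) + 1L)
    rows <- t$rows
    for (i in seq_along(set_cols)) {
      rows[keep, set_cols[i]] <- as.character(params[[i]])
    }
    con$db$tables[[tname]]$rows <- rows
    sum(keep)
  } else if (grepl("^DELETE FROM ", sql)) {
    m <- regmatches(sql, regexec("^DELETE FROM (\\S+)( WHERE (.*))?$", sql))[[1]]
    if (length(m) < 2L) fail("cannot parse DELETE")
    tname <- strip_quotes(m[2])
    t <- get_table(m[2])
    preds <- parse_where(if (length(m) >= 4L) m[4] else "")
    keep <- match_rows(t$rows, preds, params, 1L)
    con$db$tables[[tname]]$rows <- t$rows[!keep, , drop = FALSE]
    sum(keep)
  } else {
    fail("unsupported statement")
  }
}

#' Select a SQL pattern for a classified user operation
#'
#' Maps a user operation on a classified element to a statement model:
#' FetchData -> Select, Write -> Insert (all columns supplied) or Update
#' (keys plus a subset), Delete -> Delete. Predicate columns are the
#' classified key columns whose names occur among the inputs.
#'
#' @param operation_name `"FetchData"`, `"Write"` or `"Delete"`.
#' @param element_name Classified element.
#' @param inputs Named input values.
#' @param classification Element classification: a named list mapping element
#'   names to `list(table, key_columns, columns)`.
#' @return An [sql_statement()].
#' @export
select_pattern <- function(operation_name, element_name, inputs, classification) {
  cls <- classification[[element_name]]
  if (is.null(cls)) {
    mb_not_found(sprintf("element '%s' has no table classification", element_name))
  }
  inputs <- as.list(inputs)
  keys_present <- intersect(cls$key_columns, names(inputs))
  needs_keys <- operation_name %in% c("FetchData", "Delete") ||
    (operation_name == "Write" && !all(cls$columns %in% names(inputs)))
  if (needs_keys && !length(keys_present)) {
    mb_abort("mb_pattern_error",
             sprintf("no input matches a key column of '%s' (keys: %s)",
                     element_name, paste(cls$key_columns, collapse = ", ")))
  }
  preds <- lapply(keys_present, function(k) list(column = k, op = "=", value = inputs[[k]]))
  switch(operation_name,
    FetchData = sql_statement("Select", cls$table,
                              select_columns = setdiff(cls$columns, keys_present),
                              predicates = preds),
    Write = {
      if (all(cls$columns %in% names(inputs))) {
        sql_statement("Insert", cls$table,
                      assignments = inputs[cls$columns])
      } else {
        vals <- inputs[setdiff(intersect(names(inputs), cls$columns), keys_present)]
        if (!length(vals)) {
          mb_abort("mb_pattern_error",
                   sprintf("Write on '%s' supplies no non-key column", element_name))
        }
        sql_statement("Update", cls$table, assignments = vals, predicates = preds)
      }
    },
    Delete = sql_statement("Delete", cls$table, predicates = preds),
    mb_abort("mb_pattern_error",
             sprintf("no SQL pattern for operation '%s'", operation_name))
  )
}
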