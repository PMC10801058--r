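# Embedded relational query engine: a small, documented SQL subset executed
# over in-memory record tables.
#
# Grammar:
#   SELECT <item> [, <item>...] FROM <table> [WHERE <col> <op> <literal>]
#   SELECT <number>
# where <item> is '*', a column name, COUNT(*) or AGG(column) with AGG in
# COUNT/SUM/AVG/MIN/MAX; <op> is =, !=, <>, <, <=, >, >=; <literal> is a
# number or a single-quoted string. Keywords are case-insensitive.
# Failures return a structured error with a gateway error class:
# unknown table -> UNKNOWN_RELATION, unknown column -> UNKNOWN_ATTRIBUTE,
# unparseable statement -> SYNTAX, string/number comparison mismatch ->
# TYPE_MISMATCH.

sql_error <- function(error_class, detail) {
  list(ok = FALSE, error_class = error_class, detail = detail)
}

records_to_frame <- function(recs) {
  cols <- names(recs[[1]])
  out <- lapply(cols, function(cn) {
    vals <- lapply(recs, `[[`, cn)
    if (all(vapply(vals, function(v) is.null(v) || is.numeric(v), TRUE))) {
      vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    } else if (all(vapply(vals, function(v) is.null(v) || is.logical(v), TRUE))) {
      vapply(vals, function(v) if (is.null(v)) NA else v, TRUE)
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), "")
    }
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

sql_parse <- function(sql) {
  s <- trimws(sql)
  s <- sub(";\\s*$", "", s)
  m <- regexec("^[Ss][Ee][Ll][Ee][Cc][Tt]\\s+([0-9]+)$", s)
  if (length(regmatches(s, m)[[1]]) > 0) {
    return(list(kind = "const", value = as.numeric(regmatches(s, m)[[1]][2])))
  }
  m <- regexec(paste0("^[Ss][Ee][Ll][Ee][Cc][Tt]\\s+(.+?)\\s+[Ff][Rr][Oo][Mm]\\s+([A-Za-z_][A-Za-z0-9_]*)",
                      "(?:\\s+[Ww][Hh][Ee][Rr][Ee]\\s+(.+?))?\\s*$"), s)
  g <- regmatches(s, m)[[1]]
  if (!length(g)) return(sql_error("SYNTAX", sprintf("cannot parse statement: %s", sql)))
  items_raw <- trimws(strsplit(g[2], ",")[[1]])
  items <- lapply(items_raw, function(it) {
    if (it == "*") return(list(kind = "star"))
    am <- regexec("^([Cc][Oo][Uu][Nn][Tt]|[Ss][Uu][Mm]|[Aa][Vv][Gg]|[Mm][Ii][Nn]|[Mm][Aa][Xx])\\(\\s*(\\*|[A-Za-z_][A-Za-z0-9_]*)\\s*\\)$", it)
    ag <- regmatches(it, am)[[1]]
    if (length(ag)) {
      if (toupper(ag[2]) != "COUNT" && ag[3] == "*") return(sql_error("SYNTAX", sprintf("%s(*) is not valid", ag[2])))
      return(list(kind = "agg", fn = toupper(ag[2]), col = ag[3]))
    }
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", it)) return(list(kind = "col", col = it))
    sql_error("SYNTAX", sprintf("cannot parse select item '%s'", it))
  })
  bad <- Filter(function(x) isFALSE(x$ok), items)
  if (length(bad)) return(bad[[1]])
  where <- NULL
  if (!is.na(g[4]) && nzchar(g[4])) {
    wm <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*(>=|<=|!=|<>|=|<|>)\\s*('(?:[^']*)'|[+-]?[0-9]+(?:\\.[0-9]+)?)$", g[4])
    wg <- regmatches(g[4], wm)[[1]]
    if (!length(wg)) return(sql_error("SYNTAX", sprintf("cannot parse WHERE clause '%s'", g[4])))
    lit <- wg[4]
    where <- list(col = wg[2], op = wg[3],
                  value = if (startsWith(lit, "'")) substr(lit, 2, nchar(lit) - 1) else as.numeric(lit),
                  is_string = startsWith(lit, "'"))
  }
  list(kind = "select", items = items, table = g[3], where = where)
}

#' Execute a statement of the embedded SQL subset
#'
#' @param sql statement text.
#' @param tables named list of tables; each is a list of record lists or a
#'   data.frame.
#' @return on success `list(ok = TRUE, columns =, rows =)` (rows as list of
#'   lists); on failure a structured error with `error_class` and `detail`.
#' @export
sql_execute <- function(sql, tables) {
  q <- sql_parse(sql)
  if (isFALSE(q$ok)) return(q)
  if (q$kind == "const") return(list(ok = TRUE, columns = list("value"), rows = list(list(q$value))))

  if (!q$table %in% names(tables)) {
    return(sql_error("UNKNOWN_RELATION", sprintf("relation \"%s\" does not exist", q$table)))
  }
  tab <- tables[[q$table]]
  df <- if (is.data.frame(tab)) tab else records_to_frame(tab)

  if (!is.null(q$where)) {
    w <- q$where
    if (!w$col %in% names(df)) {
      return(sql_error("UNKNOWN_ATTRIBUTE", sprintf("column \"%s\" does not exist in \"%s\"", w$col, q$table)))
    }
    colv <- df[[w$col]]
    if (w$is_string != is.character(colv)) {
      return(sql_error("TYPE_MISMATCH", sprintf("cannot compare column \"%s\" with a %s literal",
                                                w$col, if (w$is_string) "string" else "numeric")))
    }
    keep <- switch(w$op,
      "="  = colv == w$value,
      "!=" = colv != w$value,
      "<>" = colv != w$value,
      "<"  = colv <  w$value,
      "<=" = colv <= w$value,
      ">"  = colv >  w$value,
      ">=" = colv >= w$value)
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
  }

  is_agg <- vapply(q$items, function(it) it$kind == "agg", TRUE)
  if (any(is_agg) && !all(is_agg)) return(sql_error("SYNTAX", "cannot mix aggregates and plain columns"))

  if (all(is_agg) && length(q$items)) {
    cols <- character(0); vals <- list()
    for (it in q$items) {
      if (it$col != "*" && !it$col %in% names(df)) {
        return(sql_error("UNKNOWN_ATTRIBUTE", sprintf("column \"%s\" does not exist in \"%s\"", it$col, q$table)))
      }
      v <- if (it$col == "*") nrow(df) else {
        x <- df[[it$col]]
        if (it$fn != "COUNT" && !is.numeric(x)) {
          return(sql_error("TYPE_MISMATCH", sprintf("%s() needs a numeric column", it$fn)))
        }
        x <- x[!is.na(x)]
        switch(it$fn,
          COUNT = length(x),
          SUM = if (length(x)) sum(x) else 0,
          AVG = if (length(x)) mean(x) else NA_real_,
          MIN = if (length(x)) min(x) else NA_real_,
          MAX = if (length(x)) max(x) else NA_real_)
      }
      cols <- c(cols, tolower(sprintf("%s_%s", it$fn, if (it$col == "*") "all" else it$col)))
      vals <- c(vals, list(v))
    }
    return(list(ok = TRUE, columns = as.list(cols), rows = list(vals)))
  }

  sel <- character(0)
  for (it in q$items) {
    if (it$kind == "star") sel <- c(sel, names(df))
    else {
      if (!it$col %in% names(df)) {
        return(sql_error("UNKNOWN_ATTRIBUTE", sprintf("column \"%s\" does not exist in \"%s\"", it$col, q$table)))
      }
      sel <- c(sel, it$col)
    }
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    lapply(sel, function(cn) { v <- df[[cn]][i]; if (is.na(v)) NULL else v })
  })
  list(ok = TRUE, columns = as.list(sel), rows = rows)
}
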