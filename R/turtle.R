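# Minimal Turtle reader/writer.
#
# Covers the subset of Turtle the schema vocabulary needs (and the subset
# rdflib emits for such graphs): @prefix declarations, IRIs, prefixed names,
# `a`, predicate-object lists with ";" and ",", string/number/boolean
# literals, optional ^^ datatypes and @lang tags, and comments. Blank nodes
# and collections are not part of the schema model and are rejected.

XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

turtle_syntax_error <- function(msg, pos = NA) {
  fs_abort("turtle_syntax", sprintf("Turtle syntax error%s: %s",
                                    if (is.na(pos)) "" else sprintf(" near offset %d", pos), msg))
}

tt_lex <- function(text) {
  pats <- c(
    ws      = "^[ \t\r\n]+",
    comment = "^#[^\n]*",
    prefix  = "^@prefix\\b",
    base    = "^@base\\b",
    sprefix = "^PREFIX\\b",
    iriref  = "^<[^<>\"{}|^`\\\\ ]*>",
    string  = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    dtmark  = "^\\^\\^",
    lang    = "^@[A-Za-z][A-Za-z0-9-]*",
    boolean = "^(?:true|false)(?![A-Za-z0-9_])",
    number  = "^[+-]?(?:[0-9]+\\.[0-9]+(?:[eE][+-]?[0-9]+)?|\\.[0-9]+(?:[eE][+-]?[0-9]+)?|[0-9]+(?:[eE][+-]?[0-9]+)?)",
    a_kw    = "^a(?![A-Za-z0-9_:-])",
    pname   = "^(?:[A-Za-z][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?",
    punct   = "^[.;,]"
  )
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (!ty %in% c("ws", "comment")) {
          tokens[[length(tokens) + 1L]] <- list(type = ty, value = substr(rest, 1L, len), pos = pos)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) turtle_syntax_error(sprintf("unexpected character '%s'", substr(rest, 1, 1)), pos)
  }
  tokens
}

tt_unescape <- function(s) {
  s <- substr(s, 2L, nchar(s) - 1L)
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\r", "\r", s)
  s <- gsub("\\\\t", "\t", s)
  s <- gsub("\\\\\"", "\"", s)
  gsub("\\\\\\\\", "\\\\", s)
}

tt_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  gsub("\t", "\\\\t", s)
}

#' Parse Turtle text into a triple table
#'
#' @param text Turtle document as a character scalar (or vector of lines).
#' @return a data.frame with columns `subject`, `predicate`, `object`,
#'   `is_iri` (logical) and `datatype` (IRI or `NA` for IRIs / plain strings).
#' @export
turtle_parse <- function(text) {
  text <- paste(text, collapse = "\n")
  toks <- tt_lex(text)
  prefixes <- character(0)
  out_s <- character(0); out_p <- character(0); out_o <- character(0)
  out_iri <- logical(0); out_dt <- character(0)
  i <- 1L
  ntok <- length(toks)
  peek <- function() if (i <= ntok) toks[[i]] else NULL
  take <- function() { t <- peek(); if (is.null(t)) turtle_syntax_error("unexpected end of input"); i <<- i + 1L; t }
  expect <- function(type, what) {
    t <- take()
    if (t$type != type) turtle_syntax_error(sprintf("expected %s, got '%s'", what, t$value), t$pos)
    t
  }

  resolve_pname <- function(tok) {
    parts <- regmatches(tok$value, regexec("^([^:]*):(.*)$", tok$value))[[1]]
    pre <- parts[2]; local <- parts[3]
    if (!pre %in% names(prefixes)) {
      turtle_syntax_error(sprintf("undeclared prefix '%s:'", pre), tok$pos)
    }
    paste0(prefixes[[pre]], local)
  }

  read_resource <- function() {
    t <- take()
    if (t$type == "iriref") return(substr(t$value, 2L, nchar(t$value) - 1L))
    if (t$type == "pname") return(resolve_pname(t))
    turtle_syntax_error(sprintf("expected an IRI, got '%s'", t$value), t$pos)
  }

  read_object <- function() {
    t <- peek()
    if (is.null(t)) turtle_syntax_error("unexpected end of input")
    if (t$type %in% c("iriref", "pname")) {
      list(value = read_resource(), is_iri = TRUE, datatype = NA_character_)
    } else if (t$type == "string") {
      take()
      dt <- NA_character_
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "dtmark") {
        take()
        dt <- read_resource()
      } else if (!is.null(nxt) && nxt$type == "lang") {
        take()
      }
      list(value = tt_unescape(t$value), is_iri = FALSE, datatype = dt)
    } else if (t$type == "number") {
      take()
      dt <- if (grepl("[.eE]", t$value)) paste0(XSD_NS, "decimal") else paste0(XSD_NS, "integer")
      list(value = t$value, is_iri = FALSE, datatype = dt)
    } else if (t$type == "boolean") {
      take()
      list(value = t$value, is_iri = FALSE, datatype = paste0(XSD_NS, "boolean"))
    } else {
      turtle_syntax_error(sprintf("expected an object term, got '%s'", t$value), t$pos)
    }
  }

  emit <- function(s, p, o) {
    out_s[length(out_s) + 1L] <<- s
    out_p[length(out_p) + 1L] <<- p
    out_o[length(out_o) + 1L] <<- o$value
    out_iri[length(out_iri) + 1L] <<- o$is_iri
    out_dt[length(out_dt) + 1L] <<- o$datatype
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type %in% c("prefix", "sprefix")) {
      take()
      ptok <- expect("pname", "a prefix name")
      pre <- sub(":.*$", "", ptok$value)
      iri <- expect("iriref", "a namespace IRI")
      prefixes[[pre]] <- substr(iri$value, 2L, nchar(iri$value) - 1L)
      if (t$type == "prefix") {
        dot <- expect("punct", "'.'")
        if (dot$value != ".") turtle_syntax_error("expected '.' after @prefix", dot$pos)
      }
      next
    }
    if (t$type == "base") turtle_syntax_error("@base is not supported", t$pos)
    subj <- read_resource()
    repeat {
      ptok <- peek()
      pred <- if (!is.null(ptok) && ptok$type == "a_kw") { take(); RDF_TYPE } else read_resource()
      repeat {
        emit(subj, pred, read_object())
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ",") { take() } else break
      }
      nxt <- take()
      if (nxt$type != "punct") turtle_syntax_error(sprintf("expected '.', ';' or ',', got '%s'", nxt$value), nxt$pos)
      if (nxt$value == ".") break
      if (nxt$value == ";") {
        # tolerate trailing ";" before "."
        nxt2 <- peek()
        if (!is.null(nxt2) && nxt2$type == "punct" && nxt2$value == ".") { take(); break }
        next
      }
      turtle_syntax_error("unexpected ','", nxt$pos)
    }
  }
  data.frame(subject = out_s, predicate = out_p, object = out_o,
             is_iri = out_iri, datatype = out_dt, stringsAsFactors = FALSE)
}

tt_format_term <- function(iri, prefixes) {
  for (pre in names(prefixes)) {
    ns <- prefixes[[pre]]
    if (startsWith(iri, ns)) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (grepl("^[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", local, perl = TRUE)) {
        return(paste0(pre, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

tt_format_object <- function(value, is_iri, datatype, prefixes) {
  if (is_iri) return(tt_format_term(value, prefixes))
  if (!is.na(datatype)) {
    if (datatype == paste0(XSD_NS, "boolean")) return(value)
    if (datatype %in% paste0(XSD_NS, c("integer", "decimal", "double")) &&
        grepl("^[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?$", value)) {
      return(value)
    }
    return(sprintf("\"%s\"^^%s", tt_escape(value), tt_format_term(datatype, prefixes)))
  }
  sprintf("\"%s\"", tt_escape(value))
}

#' Serialize a triple table as Turtle
#'
#' Subjects are written in first-appearance order, predicates grouped with
#' `;` and objects with `,`, so repeated serialization of the same triple
#' table is byte-identical.
#'
#' @param triples a data.frame as returned by [turtle_parse()].
#' @param prefixes named character vector mapping prefix -> namespace IRI.
#' @return the Turtle document as a character scalar.
#' @export
turtle_serialize <- function(triples, prefixes = c(fs = FS_NS, fsm = FS_NODE_NS,
                                                   rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                                                   xsd = XSD_NS)) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  if (!nrow(triples)) return(paste(c(header, ""), collapse = "\n"))
  lines <- character(0)
  for (subj in unique(triples$subject)) {
    rows <- triples[triples$subject == subj, , drop = FALSE]
    plines <- character(0)
    for (pred in unique(rows$predicate)) {
      prow <- rows[rows$predicate == pred, , drop = FALSE]
      objs <- vapply(seq_len(nrow(prow)), function(k) {
        tt_format_object(prow$object[k], prow$is_iri[k], prow$datatype[k], prefixes)
      }, "")
      pterm <- if (pred == RDF_TYPE) "a" else tt_format_term(pred, prefixes)
      plines <- c(plines, sprintf("    %s %s", pterm, paste(objs, collapse = ", ")))
    }
    lines <- c(lines, paste0(tt_format_term(subj, prefixes), "\n",
                             paste(plines, collapse = " ;\n"), " ."))
  }
  paste(c(header, "", lines, ""), collapse = "\n")
}
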