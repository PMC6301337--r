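# JSONTL: the transformation language ----------------------------------------
#
# Five statement types map source JSONPaths to destination paths:
#
#   let "dest" = "literal";
#   transform column  "src" to "dest" [assign name from "src2"] [apply ...];
#   transform columns "s1", "s2" to "dest" apply ...;          (apply required)
#   transform union   "s1", "s2" to "dest" [apply ...];
#   join "s1", "s2" to "dest" [apply ...];
#
# Any statement except join may be prefixed with `if <condition> then`.
# An apply section is either a verbatim `{{ ... }}` block (run in the
# sandboxed block interpreter) or a registered function call like
# toStandardDateTime("yyyy-MM-dd"). Keywords are case-insensitive; `//`
# comments run to end of line outside blocks and strings.

TL_KEYWORDS <- c("let", "transform", "column", "columns", "union", "join",
                 "to", "apply", "assign", "name", "from", "if", "then",
                 "and", "or", "like", "exists", "not")

# -- lexer -------------------------------------------------------------------

tl_lex <- function(text, keywords = TL_KEYWORDS) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L; line <- 1L; col <- 1L
  adv <- function(k = 1L) {
    for (j in seq_len(k)) {
      if (i <= n && chars[i] == "\n") { line <<- line + 1L; col <<- 1L }
      else col <<- col + 1L
      i <<- i + 1L
    }
  }
  peek2 <- function() if (i + 1L <= n) paste0(chars[i], chars[i + 1L]) else ""
  emit <- function(type, value, l = line, c = col) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       line = l, col = c)
  }
  lex_fail <- function(...) {
    stop_parse("JSONTL lexical error at line ", line, ", col ", col, ": ", ...)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) { adv(); next }
    if (peek2() == "//") {
      while (i <= n && chars[i] != "\n") adv()
      next
    }
    if (peek2() == "{{") {
      l0 <- line; c0 <- col
      adv(2L)
      start <- i
      while (i <= n && peek2() != "}}") adv()
      if (i > n) { line <- l0; col <- c0; lex_fail("unterminated {{ block") }
      code <- paste(chars[start:(i - 1L)], collapse = "")
      adv(2L)
      emit("BLOCK", code, l0, c0)
      next
    }
    if (ch == '"') {
      l0 <- line; c0 <- col
      adv()
      out <- character(0)
      repeat {
        if (i > n) { line <- l0; col <- c0; lex_fail("unterminated string") }
        ch <- chars[i]
        if (ch == '"') { adv(); break }
        if (ch == "\\" && i < n) {
          nxt <- chars[i + 1L]
          rep <- switch(nxt, "n" = "\n", "t" = "\t", '"' = '"',
                        "\\" = "\\", NULL)
          if (is.null(rep)) rep <- paste0("\\", nxt) # unknown escape kept
          out <- c(out, rep)
          adv(2L)
        } else {
          out <- c(out, ch)
          adv()
        }
      }
      emit("STRING", paste(out, collapse = ""), l0, c0)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      l0 <- line; c0 <- col
      start <- i
      while (i <= n && grepl("^[A-Za-z0-9_]$", chars[i])) adv()
      word <- paste(chars[start:(i - 1L)], collapse = "")
      if (tolower(word) %in% keywords) emit("KW", tolower(word), l0, c0)
      else emit("NAME", word, l0, c0)
      next
    }
    two <- peek2()
    if (two %in% c("!=", "<=", ">=", "==")) {
      emit("OP", two); adv(2L); next
    }
    if (ch %in% c("=", "<", ">")) { emit("OP", ch); adv(); next }
    if (ch %in% c(";", ",", "(", ")")) { emit("PUNCT", ch); adv(); next }
    lex_fail("unexpected character '", ch, "'")
  }
  toks
}

# -- token stream helpers ----------------------------------------------------

tl_stream <- function(toks, src = "") {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  env$src <- src
  env
}

tl_peek <- function(ts) if (ts$pos <= length(ts$toks)) ts$toks[[ts$pos]] else NULL

tl_next <- function(ts) {
  tk <- tl_peek(ts)
  if (is.null(tk)) tl_error(ts, "unexpected end of input")
  ts$pos <- ts$pos + 1L
  tk
}

tl_error <- function(ts, ...) {
  tk <- tl_peek(ts)
  where <- if (is.null(tk)) "at end of input"
           else paste0("at line ", tk$line, ", col ", tk$col,
                       " near '", tk$value, "'")
  stop_parse("JSONTL syntax error ", where, ": ", ...)
}

tl_expect <- function(ts, type, value = NULL) {
  tk <- tl_peek(ts)
  ok <- !is.null(tk) && tk$type == type &&
    (is.null(value) || identical(tk$value, value))
  if (!ok) tl_error(ts, "expected ", if (is.null(value)) type else value)
  tl_next(ts)
}

tl_at_kw <- function(ts, kw) {
  tk <- tl_peek(ts)
  !is.null(tk) && tk$type == "KW" && tk$value %in% kw
}

# -- parser ------------------------------------------------------------------

#' Parse a JSONTL transformation script
#'
#' @param text script source text, or a path to a `.trl` file.
#' @return a `tl_script`: an ordered list of parsed statements.
#' @export
#' @examples
#' parse_script('let "dataRepository.name" = "Protein Data Bank";')
parse_script <- function(text) {
  if (length(text) == 1L && !grepl("[;{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  ts <- tl_stream(tl_lex(text), text)
  stmts <- list()
  while (!is.null(tl_peek(ts))) {
    stmts[[length(stmts) + 1L]] <- tl_parse_statement(ts)
  }
  structure(list(statements = stmts), class = "tl_script")
}

tl_parse_statement <- function(ts) {
  if (tl_at_kw(ts, "if")) {
    tl_next(ts)
    cond <- tl_parse_cond_or(ts)
    tl_expect(ts, "KW", "then")
    stmt <- tl_parse_statement(ts)
    if (stmt$type == "join") {
      tl_error(ts, "a join statement cannot carry a condition")
    }
    if (!is.null(stmt$condition)) {
      tl_error(ts, "nested conditions are not supported")
    }
    stmt$condition <- cond
    return(stmt)
  }
  tk <- tl_peek(ts)
  if (is.null(tk)) tl_error(ts, "expected a statement")
  if (tk$type != "KW") tl_error(ts, "expected a statement keyword")
  switch(tk$value,
         "let" = tl_parse_let(ts),
         "transform" = tl_parse_transform(ts),
         "join" = tl_parse_join(ts),
         tl_error(ts, "unknown statement keyword '", tk$value, "'"))
}

tl_parse_let <- function(ts) {
  tl_expect(ts, "KW", "let")
  dest <- tl_expect(ts, "STRING")$value
  tl_expect(ts, "OP", "=")
  lit <- tl_expect(ts, "STRING")$value
  tl_expect(ts, "PUNCT", ";")
  tl_stmt("constant", dest = dest, literal = lit)
}

tl_parse_source_list <- function(ts) {
  out <- character(0)
  repeat {
    out <- c(out, tl_expect(ts, "STRING")$value)
    tk <- tl_peek(ts)
    if (!is.null(tk) && tk$type == "PUNCT" && tk$value == ",") tl_next(ts)
    else break
  }
  out
}

tl_parse_transform <- function(ts) {
  tl_expect(ts, "KW", "transform")
  tk <- tl_next(ts)
  if (tk$type != "KW" || !tk$value %in% c("column", "columns", "union")) {
    tl_error(ts, "expected 'column', 'columns' or 'union' after 'transform'")
  }
  kind <- tk$value
  sources <- tl_parse_source_list(ts)
  if (kind == "column" && length(sources) != 1L) {
    tl_error(ts, "'transform column' takes exactly one source path")
  }
  tl_expect(ts, "KW", "to")
  dest <- tl_expect(ts, "STRING")$value
  anf <- NULL
  if (kind == "column" && tl_at_kw(ts, "assign")) {
    tl_next(ts)
    tl_expect(ts, "KW", "name")
    tl_expect(ts, "KW", "from")
    anf <- tl_expect(ts, "STRING")$value
  }
  ap <- tl_parse_apply_opt(ts)
  tl_expect(ts, "PUNCT", ";")
  if (kind == "columns" && is.null(ap)) {
    tl_error(ts, "'transform columns' requires an apply section")
  }
  switch(kind,
         column = tl_stmt("single", sources = sources, dest = dest,
                          assign_name_from = anf, apply = ap),
         columns = tl_stmt("columns", sources = sources, dest = dest,
                           apply = ap),
         union = tl_stmt("union", sources = sources, dest = dest, apply = ap))
}

tl_parse_join <- function(ts) {
  tl_expect(ts, "KW", "join")
  sources <- tl_parse_source_list(ts)
  tl_expect(ts, "KW", "to")
  dest <- tl_expect(ts, "STRING")$value
  ap <- tl_parse_apply_opt(ts)
  tl_expect(ts, "PUNCT", ";")
  tl_stmt("join", sources = sources, dest = dest, apply = ap)
}

tl_parse_apply_opt <- function(ts) {
  if (!tl_at_kw(ts, "apply")) return(NULL)
  tl_next(ts)
  tk <- tl_peek(ts)
  if (is.null(tk)) tl_error(ts, "expected an apply block or function call")
  if (tk$type == "BLOCK") {
    tl_next(ts)
    return(list(kind = "script", code = tk$value))
  }
  if (tk$type == "NAME") {
    nm <- tl_next(ts)$value
    tl_expect(ts, "PUNCT", "(")
    args <- character(0)
    if (!identical(tl_peek(ts)$value, ")")) {
      repeat {
        args <- c(args, tl_expect(ts, "STRING")$value)
        if (identical(tl_peek(ts)$value, ",")) tl_next(ts) else break
      }
    }
    tl_expect(ts, "PUNCT", ")")
    return(list(kind = "function", name = nm, args = args))
  }
  tl_error(ts, "expected a {{ }} block or a function call after 'apply'")
}

tl_stmt <- function(type, dest, sources = NULL, literal = NULL,
                    assign_name_from = NULL, apply = NULL, condition = NULL) {
  structure(list(
    type = type,
    dest_text = dest,
    dest = parse_dest_path(dest),
    source_texts = sources,
    sources = if (is.null(sources)) NULL else lapply(sources, parse_source_path),
    literal = literal,
    assign_name_from_text = assign_name_from,
    assign_name_from = if (is.null(assign_name_from)) NULL
                       else parse_source_path(assign_name_from),
    apply = apply,
    condition = condition
  ), class = "tl_statement")
}

# -- conditions --------------------------------------------------------------

#' Parse a standalone JSONTL condition
#'
#' Comparisons (`=`, `!=`, `<`, `>`, `<=`, `>=`, `like`, `exists`,
#' `not exists`) over source paths, combined with `and`/`or` (`and` binds
#' tighter) and parentheses. `like` literals use `%` wildcards.
#'
#' @param text condition source, e.g. `'"$.'SourceAccession'" like "%GSE%"'`.
#' @return a compiled condition tree.
#' @export
parse_condition <- function(text) {
  ts <- tl_stream(tl_lex(text), text)
  cond <- tl_parse_cond_or(ts)
  if (!is.null(tl_peek(ts))) tl_error(ts, "trailing input after condition")
  cond
}

tl_parse_cond_or <- function(ts) {
  left <- tl_parse_cond_and(ts)
  args <- list(left)
  while (tl_at_kw(ts, "or")) {
    tl_next(ts)
    args[[length(args) + 1L]] <- tl_parse_cond_and(ts)
  }
  if (length(args) == 1L) left else list(type = "or", args = args)
}

tl_parse_cond_and <- function(ts) {
  left <- tl_parse_cond_prim(ts)
  args <- list(left)
  while (tl_at_kw(ts, "and")) {
    tl_next(ts)
    args[[length(args) + 1L]] <- tl_parse_cond_prim(ts)
  }
  if (length(args) == 1L) left else list(type = "and", args = args)
}

tl_parse_cond_prim <- function(ts) {
  tk <- tl_peek(ts)
  if (!is.null(tk) && tk$type == "PUNCT" && tk$value == "(") {
    tl_next(ts)
    inner <- tl_parse_cond_or(ts)
    tl_expect(ts, "PUNCT", ")")
    return(inner)
  }
  path_text <- tl_expect(ts, "STRING")$value
  path <- parse_source_path(path_text)
  tk <- tl_peek(ts)
  if (is.null(tk)) tl_error(ts, "expected a comparison operator")
  if (tk$type == "OP") {
    op <- switch(tl_next(ts)$value,
                 "=" = "eq", "!=" = "ne", "<" = "lt", ">" = "gt",
                 "<=" = "le", ">=" = "ge")
    lit <- tl_expect(ts, "STRING")$value
    return(list(type = "cmp", op = op, path = path, path_text = path_text,
                literal = lit))
  }
  if (tk$type == "KW" && tk$value == "like") {
    tl_next(ts)
    lit <- tl_expect(ts, "STRING")$value
    return(list(type = "cmp", op = "like", path = path,
                path_text = path_text, literal = lit))
  }
  if (tk$type == "KW" && tk$value == "exists") {
    tl_next(ts)
    return(list(type = "cmp", op = "exists", path = path,
                path_text = path_text, literal = NULL))
  }
  if (tk$type == "KW" && tk$value == "not") {
    tl_next(ts)
    tl_expect(ts, "KW", "exists")
    return(list(type = "cmp", op = "not_exists", path = path,
                path_text = path_text, literal = NULL))
  }
  tl_error(ts, "unknown condition operator")
}

# -- unparse -----------------------------------------------------------------

tl_quote <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub('"', '\\"', s, fixed = TRUE)
  paste0('"', s, '"')
}

unparse_condition <- function(cond) {
  if (cond$type == "cmp") {
    p <- tl_quote(unparse_source_path(cond$path))
    return(switch(cond$op,
      exists = paste(p, "exists"),
      not_exists = paste(p, "not exists"),
      like = paste(p, "like", tl_quote(cond$literal)),
      paste(p, switch(cond$op, eq = "=", ne = "!=", lt = "<", gt = ">",
                      le = "<=", ge = ">="), tl_quote(cond$literal))))
  }
  inner <- vapply(cond$args, function(a) {
    s <- unparse_condition(a)
    if (a$type == "cmp") s else paste0("(", s, ")")
  }, character(1))
  paste(inner, collapse = paste0(" ", cond$type, " "))
}

unparse_apply <- function(ap) {
  if (is.null(ap)) return("")
  if (ap$kind == "script") return(paste0(" apply {{", ap$code, "}}"))
  paste0(" apply ", ap$name, "(",
         paste(vapply(ap$args, tl_quote, character(1)), collapse = ", "), ")")
}

#' Render a parsed statement or script back to JSONTL source
#'
#' @param x a `tl_statement` or `tl_script`.
#' @return source text that reparses to a structurally equal AST.
#' @export
unparse_statement <- function(x) {
  body <- switch(x$type,
    constant = paste0("let ", tl_quote(unparse_dest_path(x$dest)), " = ",
                      tl_quote(x$literal), ";"),
    single = paste0("transform column ",
                    tl_quote(unparse_source_path(x$sources[[1L]])),
                    " to ", tl_quote(unparse_dest_path(x$dest)),
                    if (!is.null(x$assign_name_from))
                      paste0(" assign name from ",
                             tl_quote(unparse_source_path(x$assign_name_from)))
                    else "",
                    unparse_apply(x$apply), ";"),
    columns = paste0("transform columns ",
                     paste(vapply(x$sources, function(p)
                       tl_quote(unparse_source_path(p)), character(1)),
                       collapse = ", "),
                     " to ", tl_quote(unparse_dest_path(x$dest)),
                     unparse_apply(x$apply), ";"),
    union = paste0("transform union ",
                   paste(vapply(x$sources, function(p)
                     tl_quote(unparse_source_path(p)), character(1)),
                     collapse = ", "),
                   " to ", tl_quote(unparse_dest_path(x$dest)),
                   unparse_apply(x$apply), ";"),
    join = paste0("join ",
                  paste(vapply(x$sources, function(p)
                    tl_quote(unparse_source_path(p)), character(1)),
                    collapse = ", "),
                  " to ", tl_quote(unparse_dest_path(x$dest)),
                  unparse_apply(x$apply), ";"))
  if (!is.null(x$condition)) {
    body <- paste0("if ", unparse_condition(x$condition), " then ", body)
  }
  body
}

#' @rdname unparse_statement
#' @export
unparse_script <- function(x) {
  paste(vapply(x$statements, unparse_statement, character(1)),
        collapse = "\n")
}

#' @export
print.tl_script <- function(x, ...) {
  cat("<JSONTL script: ", length(x$statements), " statement(s)>\n", sep = "")
  cat(unparse_script(x), "\n")
  invisible(x)
}

#' @export
print.tl_statement <- function(x, ...) {
  cat(unparse_statement(x), "\n")
  invisible(x)
}
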