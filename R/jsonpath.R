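# JSONPath subset ------------------------------------------------------------
#
# Source paths select nodes in a document tree; destination paths construct
# branches in a new tree. The recognized subset: root `$`, `.`-separated bare
# or single-quoted names, `..` deep scan, `[*]`, `[n]`, and equality filters
# `[?(@.'name' = 'lit')]`. Destination paths: dot-separated names with
# optional `[]` (append) or `[i]` (index) suffixes.

BARE_NAME_RE <- "[A-Za-z0-9_@:$-]+"

# -- scanner -----------------------------------------------------------------

jp_scanner <- function(text) {
  env <- new.env(parent = emptyenv())
  env$s <- text
  env$pos <- 1L
  env$n <- nchar(text)
  env
}

jp_peek <- function(sc, k = 1L) {
  if (sc$pos + k - 1L > sc$n) return("")
  substr(sc$s, sc$pos, sc$pos + k - 1L)
}

jp_take <- function(sc, k = 1L) {
  out <- jp_peek(sc, k)
  sc$pos <- sc$pos + k
  out
}

jp_fail <- function(sc, ...) {
  stop_parse("path syntax error at position ", sc$pos, " in \"", sc$s,
             "\": ", ...)
}

jp_name <- function(sc, quote_char = "'") {
  if (jp_peek(sc) == quote_char) {
    jp_take(sc)
    start <- sc$pos
    while (sc$pos <= sc$n && jp_peek(sc) != quote_char) sc$pos <- sc$pos + 1L
    if (sc$pos > sc$n) jp_fail(sc, "unterminated quoted name")
    nm <- substr(sc$s, start, sc$pos - 1L)
    jp_take(sc)
    return(nm)
  }
  m <- regmatches(substr(sc$s, sc$pos, sc$n),
                  regexpr(paste0("^", BARE_NAME_RE), substr(sc$s, sc$pos, sc$n)))
  if (length(m) == 0L || !nzchar(m)) jp_fail(sc, "expected a name")
  sc$pos <- sc$pos + nchar(m)
  m
}

jp_skip_ws <- function(sc) {
  while (sc$pos <= sc$n && grepl("^[ \t]$", jp_peek(sc))) sc$pos <- sc$pos + 1L
}

# -- source path parsing -----------------------------------------------------

#' Parse a source JSONPath expression
#'
#' Accepts `$`, dot-separated single-quoted or bare names, `..` deep scan,
#' `[*]` wildcards, `[n]` indices and filters of the form
#' `[?(@.'name' = 'literal')]` (operators `=`/`==` and `!=`).
#'
#' @param text the path string.
#' @return a compiled path of class `jp_source_path`.
#' @export
#' @examples
#' parse_source_path("$..'rev'[?(@.'@num' = '1')].'date'.'_$'")
parse_source_path <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  sc <- jp_scanner(trimws(text))
  if (jp_take(sc) != "$") jp_fail(sc, "source path must start with '$'")
  steps <- list()
  while (sc$pos <= sc$n) {
    kind <- if (jp_peek(sc, 2L) == "..") { jp_take(sc, 2L); "deep" }
            else if (jp_peek(sc) == ".") { jp_take(sc); "child" }
            else jp_fail(sc, "expected '.' or '..'")
    nm <- jp_name(sc)
    ops <- list()
    while (jp_peek(sc) == "[") {
      ops[[length(ops) + 1L]] <- jp_bracket_op(sc)
    }
    steps[[length(steps) + 1L]] <- list(kind = kind, name = nm, ops = ops)
  }
  structure(list(steps = steps, text = text), class = "jp_source_path")
}

jp_bracket_op <- function(sc) {
  jp_take(sc) # '['
  ch <- jp_peek(sc)
  if (ch == "*") {
    jp_take(sc)
    if (jp_take(sc) != "]") jp_fail(sc, "expected ']' after '*'")
    return(list(kind = "wildcard"))
  }
  if (grepl("^[0-9]$", ch)) {
    start <- sc$pos
    while (grepl("^[0-9]$", jp_peek(sc))) sc$pos <- sc$pos + 1L
    i <- as.integer(substr(sc$s, start, sc$pos - 1L))
    if (jp_take(sc) != "]") jp_fail(sc, "expected ']' after index")
    return(list(kind = "index", i = i))
  }
  if (ch == "?") {
    jp_take(sc)
    if (jp_take(sc) != "(") jp_fail(sc, "expected '(' after '?'")
    jp_skip_ws(sc)
    if (jp_take(sc) != "@") jp_fail(sc, "filter must start with '@'")
    rel <- character(0)
    while (jp_peek(sc) == ".") {
      jp_take(sc)
      rel <- c(rel, jp_name(sc))
    }
    if (length(rel) == 0L) jp_fail(sc, "filter needs a relative path")
    jp_skip_ws(sc)
    op <- if (jp_peek(sc, 2L) == "==") { jp_take(sc, 2L); "eq" }
          else if (jp_peek(sc, 2L) == "!=") { jp_take(sc, 2L); "ne" }
          else if (jp_peek(sc) == "=") { jp_take(sc); "eq" }
          else jp_fail(sc, "unknown filter operator (only = and != supported)")
    jp_skip_ws(sc)
    if (jp_peek(sc) != "'") jp_fail(sc, "filter literal must be single-quoted")
    lit <- jp_name(sc) # consumes the quoted literal
    jp_skip_ws(sc)
    if (jp_take(sc) != ")") jp_fail(sc, "expected ')'")
    if (jp_take(sc) != "]") jp_fail(sc, "expected ']'")
    return(list(kind = "filter", rel = rel, op = op, literal = lit))
  }
  jp_fail(sc, "expected '*', an index, or '?(' inside brackets")
}

#' @export
format.jp_source_path <- function(x, ...) unparse_source_path(x)

#' @export
print.jp_source_path <- function(x, ...) {
  cat("<source path> ", unparse_source_path(x), "\n", sep = "")
  invisible(x)
}

#' Render a compiled source path back to canonical text
#'
#' @param path a `jp_source_path`.
#' @return the canonical path string (all names quoted).
#' @export
unparse_source_path <- function(path) {
  out <- "$"
  for (st in path$steps) {
    out <- paste0(out, if (st$kind == "deep") ".." else ".",
                  "'", st$name, "'")
    for (op in st$ops) {
      out <- paste0(out, switch(op$kind,
        wildcard = "[*]",
        index = paste0("[", op$i, "]"),
        filter = paste0("[?(@.", paste0("'", op$rel, "'", collapse = "."),
                        " ", if (op$op == "eq") "=" else "!=",
                        " '", op$literal, "')]")))
    }
  }
  out
}

# -- matching ----------------------------------------------------------------

scalar_text <- function(x) {
  if (is.character(x)) return(x)
  if (is.logical(x)) return(if (isTRUE(x)) "true" else "false")
  format(unclass(x), digits = 15, scientific = FALSE, trim = TRUE)
}

# strict child resolution for filter predicates (objects only)
jp_resolve_rel <- function(node, rel) {
  for (nm in rel) {
    if (!is_tree_object(node)) return(NULL)
    if (!nm %in% names(node)) return(NULL)
    node <- node[[nm]]
  }
  node
}

jp_filter_ok <- function(node, op) {
  v <- jp_resolve_rel(node, op$rel)
  if (is.null(v) || !is_tree_scalar(v)) return(FALSE)
  eq <- identical(scalar_text(v), op$literal)
  if (op$op == "eq") eq else !eq
}

#' Evaluate a source path against a document tree
#'
#' Returns all matches in document order. Deep scan (`..`) matches the named
#' member at any depth (including under arrays); `[*]` iterates array
#' elements; a child step applied to an array distributes over its elements;
#' filters keep candidates whose relative path resolves to a scalar equal
#' (or unequal) to the literal, with scalars stringified before comparison.
#' Absence of a match yields an empty list, never an error.
#'
#' @param tree a document tree.
#' @param path a `jp_source_path` (or path string, parsed on the fly).
#' @return list of matches, each `list(value=, location=)`; `location` is the
#'   concrete member-name / 0-based-index step list from the root.
#' @export
jp_match <- function(tree, path) {
  if (is.character(path)) path <- parse_source_path(path)
  stopifnot(inherits(path, "jp_source_path"))
  cands <- list(list(value = tree, location = list()))
  for (st in path$steps) {
    nxt <- list()
    for (cd in cands) {
      hits <- if (st$kind == "child") jp_child(cd, st$name) else jp_deep(cd, st$name)
      nxt <- c(nxt, hits)
    }
    for (op in st$ops) {
      after <- list()
      for (cd in nxt) after <- c(after, jp_apply_op(cd, op))
      nxt <- after
    }
    cands <- nxt
    if (length(cands) == 0L) break
  }
  cands
}

jp_child <- function(cd, name) {
  node <- cd$value
  if (is_tree_object(node)) {
    if (name %in% names(node)) {
      return(list(list(value = node[[name]],
                       location = c(cd$location, list(name)))))
    }
    return(list())
  }
  if (is_tree_array(node)) {
    out <- list()
    for (i in seq_along(node)) {
      el <- node[[i]]
      if (is_tree_object(el) && name %in% names(el)) {
        out[[length(out) + 1L]] <- list(
          value = el[[name]],
          location = c(cd$location, list(i - 1L, name)))
      }
    }
    return(out)
  }
  list()
}

jp_deep <- function(cd, name) {
  out <- list()
  walk <- function(node, loc) {
    if (is_tree_object(node)) {
      if (name %in% names(node)) {
        out[[length(out) + 1L]] <<- list(value = node[[name]],
                                         location = c(loc, list(name)))
      }
      for (nm in names(node)) walk(node[[nm]], c(loc, list(nm)))
    } else if (is_tree_array(node)) {
      for (i in seq_along(node)) walk(node[[i]], c(loc, list(i - 1L)))
    }
  }
  walk(cd$value, cd$location)
  out
}

jp_apply_op <- function(cd, op) {
  node <- cd$value
  if (op$kind == "wildcard") {
    if (is_tree_array(node)) {
      return(lapply(seq_along(node), function(i) {
        list(value = node[[i]], location = c(cd$location, list(i - 1L)))
      }))
    }
    return(list(cd)) # singleton semantics for non-arrays
  }
  if (op$kind == "index") {
    if (is_tree_array(node)) {
      if (op$i < length(node)) {
        return(list(list(value = node[[op$i + 1L]],
                         location = c(cd$location, list(op$i)))))
      }
      return(list())
    }
    if (op$i == 0L) return(list(cd)) # singleton
    return(list())
  }
  # filter
  if (is_tree_array(node)) {
    out <- list()
    for (i in seq_along(node)) {
      if (jp_filter_ok(node[[i]], op)) {
        out[[length(out) + 1L]] <- list(value = node[[i]],
                                        location = c(cd$location, list(i - 1L)))
      }
    }
    return(out)
  }
  if (jp_filter_ok(node, op)) return(list(cd))
  list()
}

#' Resolve a concrete match location against a tree
#'
#' @param tree a document tree.
#' @param location step list as produced by [jp_match()] (member names and
#'   0-based array indices).
#' @return the node at that location, or `NULL` if the location is dangling.
#' @export
jp_resolve_location <- function(tree, location) {
  node <- tree
  for (stp in location) {
    if (is.character(stp)) {
      if (!is_tree_object(node) || !stp %in% names(node)) return(NULL)
      node <- node[[stp]]
    } else {
      if (!is_tree_array(node) || stp + 1L > length(node)) return(NULL)
      node <- node[[stp + 1L]]
    }
  }
  node
}

# -- destination paths -------------------------------------------------------

#' Parse a destination path
#'
#' Dot-separated names with optional `[]` (append a new array element) or
#' `[i]` (write at index `i`, 0-based) suffixes; an optional leading `$.` is
#' tolerated.
#'
#' @param text the path string, e.g. `"identifiers[].ID"`.
#' @return a compiled path of class `jp_dest_path`.
#' @export
parse_dest_path <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- trimws(text)
  sc <- jp_scanner(sub("^\\$\\.", "", src))
  steps <- list()
  repeat {
    nm <- jp_name(sc)
    step <- list(kind = "child", name = nm)
    if (jp_peek(sc) == "[") {
      jp_take(sc)
      if (jp_peek(sc) == "]") {
        jp_take(sc)
        step <- list(kind = "append", name = nm)
      } else {
        start <- sc$pos
        while (grepl("^[0-9]$", jp_peek(sc))) sc$pos <- sc$pos + 1L
        if (sc$pos == start) jp_fail(sc, "expected index or ']'")
        step <- list(kind = "at", name = nm,
                     i = as.integer(substr(sc$s, start, sc$pos - 1L)))
        if (jp_take(sc) != "]") jp_fail(sc, "expected ']'")
      }
    }
    steps[[length(steps) + 1L]] <- step
    if (sc$pos > sc$n) break
    if (jp_take(sc) != ".") jp_fail(sc, "expected '.'")
  }
  structure(list(steps = steps, text = text), class = "jp_dest_path")
}

#' @export
format.jp_dest_path <- function(x, ...) unparse_dest_path(x)

#' @export
print.jp_dest_path <- function(x, ...) {
  cat("<dest path> ", unparse_dest_path(x), "\n", sep = "")
  invisible(x)
}

#' Render a compiled destination path back to text
#' @param path a `jp_dest_path`.
#' @return the canonical path string.
#' @export
unparse_dest_path <- function(path) {
  paste(vapply(path$steps, function(st) {
    nm <- if (grepl(paste0("^", BARE_NAME_RE, "$"), st$name)) st$name
          else paste0("'", st$name, "'")
    switch(st$kind,
           child = nm,
           append = paste0(nm, "[]"),
           at = paste0(nm, "[", st$i, "]"))
  }, character(1)), collapse = ".")
}

#' Write a value into a tree along a destination path
#'
#' Missing intermediate objects and arrays are created. `name[]` appends a
#' new element to the named array (creating it if absent); `name[i]` writes
#' at index `i`, padding with empty objects; a plain name overwrites.
#'
#' @param tree destination tree (an object node; an empty object if starting
#'   fresh).
#' @param path a `jp_dest_path` or path string.
#' @param value the document tree (often a scalar) to write.
#' @return the modified tree.
#' @export
#' @examples
#' set_value(tree_object(), "dataRepository.name", "Protein Data Bank")
set_value <- function(tree, path, value) {
  if (is.character(path)) path <- parse_dest_path(path)
  stopifnot(inherits(path, "jp_dest_path"))
  if (is.null(tree)) tree <- tree_object()
  set_value_rec(tree, path$steps, value, path)
}

set_value_rec <- function(node, steps, value, path) {
  if (length(steps) == 0L) return(value)
  st <- steps[[1L]]
  rest <- steps[-1L]
  if (is.null(node)) node <- tree_object()
  if (!is_tree_object(node)) {
    stop_transform("type conflict writing member '", st$name,
                   "' under a non-object node (path ",
                   unparse_dest_path(path), ")")
  }
  cur <- if (st$name %in% names(node)) node[[st$name]] else NULL
  if (st$kind == "child") {
    node[[st$name]] <- set_value_rec(cur, rest, value, path)
    return(node)
  }
  if (is.null(cur)) cur <- tree_array()
  if (!is_tree_array(cur)) {
    stop_transform("type conflict: '", st$name, "' exists and is not an ",
                   "array (path ", unparse_dest_path(path), ")")
  }
  if (st$kind == "append") {
    cur[[length(cur) + 1L]] <- set_value_rec(NULL, rest, value, path)
  } else { # at
    while (length(cur) < st$i + 1L) cur[[length(cur) + 1L]] <- tree_object()
    cur[[st$i + 1L]] <- set_value_rec(cur[[st$i + 1L]], rest, value, path)
  }
  names(cur) <- NULL
  node[[st$name]] <- cur
  node
}
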