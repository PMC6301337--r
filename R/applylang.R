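# Apply-block interpreter ----------------------------------------------------
#
# JSONTL apply blocks are written in a small imperative dialect (Python-style
# surface): assignment, string/number/list expressions, `a if cond else b`
# conditionals, try/except, `pass`, 0-based indexing, the methods
# extend/append/index/strip/split/lower/upper/replace/startswith/join, the
# builtins len/str/int, and a regex facility addressable as `re.split` /
# `re.sub`. Blocks run in a closed sandbox: the only names visible are the
# statement bindings (value, value1..N, ...) plus those builtins — no I/O,
# no imports. The block must define `result`.

# -- lexer -------------------------------------------------------------------

al_lex <- function(text) {
  # normalize typographic quotes that sneak into copied scripts
  text <- chartr("‘’“”", "''\"\"", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  emit <- function(type, value) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      q <- ch
      i <- i + 1L
      out <- character(0)
      while (i <= n && chars[i] != q) {
        if (chars[i] == "\\" && i < n) {
          nxt <- chars[i + 1L]
          rep <- switch(nxt, "n" = "\n", "t" = "\t", "'" = "'", '"' = '"',
                        "\\" = "\\", NULL)
          if (is.null(rep)) rep <- paste0("\\", nxt)
          out <- c(out, rep)
          i <- i + 2L
        } else {
          out <- c(out, chars[i])
          i <- i + 1L
        }
      }
      if (i > n) al_error("unterminated string in apply block")
      i <- i + 1L
      emit("STR", paste(out, collapse = ""))
      next
    }
    if (grepl("^[0-9]$", ch)) {
      start <- i
      while (i <= n && grepl("^[0-9.]$", chars[i])) i <- i + 1L
      emit("NUM", as.numeric(paste(chars[start:(i - 1L)], collapse = "")))
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      start <- i
      while (i <= n && grepl("^[A-Za-z0-9_]$", chars[i])) i <- i + 1L
      emit("NAME", paste(chars[start:(i - 1L)], collapse = ""))
      next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("==", "!=", "<=", ">=")) {
      emit("OP", two); i <- i + 2L; next
    }
    if (ch %in% c("+", "-", "*", "/", "%", "<", ">", "=", "(", ")", "[", "]",
                  ",", ".", ":")) {
      emit("OP", ch); i <- i + 1L; next
    }
    al_error("unexpected character '", ch, "' in apply block")
  }
  toks
}

al_error <- function(...) crucible_stop("crucible_apply_error", ...)

# raisable (catchable by try/except) runtime errors
al_raise <- function(...) {
  stop(structure(class = c("al_runtime_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# -- statement-level parsing (line/indent structured) ------------------------

al_parse_program <- function(code) {
  raw <- strsplit(code, "\n", fixed = TRUE)[[1]]
  lines <- list()
  for (ln in raw) {
    if (!nzchar(trimws(ln))) next
    indent <- nchar(sub("[^ \t].*$", "", ln))
    lines[[length(lines) + 1L]] <- list(indent = indent, text = trimws(ln))
  }
  res <- al_parse_stmts(lines, 1L, -1L)
  if (res$i <= length(lines)) al_error("could not parse apply block")
  res$stmts
}

al_parse_stmts <- function(lines, i, min_indent) {
  stmts <- list()
  base <- NULL
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (ln$indent <= min_indent) break
    if (is.null(base)) base <- ln$indent
    if (ln$indent < base) break
    if (grepl("^try\\s*:", ln$text)) {
      parsed <- al_parse_try(lines, i, base)
      stmts[[length(stmts) + 1L]] <- parsed$stmt
      i <- parsed$i
      next
    }
    stmts[[length(stmts) + 1L]] <- al_parse_simple(ln$text)
    i <- i + 1L
  }
  list(stmts = stmts, i = i)
}

al_parse_try <- function(lines, i, base) {
  header_indent <- lines[[i]]$indent
  i <- i + 1L
  # try body: indented block if present, else statements until 'except'
  if (i <= length(lines) && lines[[i]]$indent > header_indent) {
    res <- al_parse_stmts(lines, i, header_indent)
    body <- res$stmts
    i <- res$i
  } else {
    body <- list()
    while (i <= length(lines) && !grepl("^except\\b", lines[[i]]$text)) {
      body[[length(body) + 1L]] <- al_parse_simple(lines[[i]]$text)
      i <- i + 1L
    }
  }
  if (i > length(lines) || !grepl("^except\\b", lines[[i]]$text)) {
    al_error("'try' without matching 'except'")
  }
  i <- i + 1L
  if (i <= length(lines) && lines[[i]]$indent > header_indent) {
    res <- al_parse_stmts(lines, i, header_indent)
    handler <- res$stmts
    i <- res$i
  } else if (i <= length(lines)) {
    handler <- list(al_parse_simple(lines[[i]]$text))
    i <- i + 1L
  } else {
    handler <- list()
  }
  list(stmt = list(type = "try", body = body, handler = handler), i = i)
}

al_parse_simple <- function(text) {
  if (identical(text, "pass")) return(list(type = "pass"))
  toks <- al_lex(text)
  # NAME '=' ... (single '=' only) is an assignment
  if (length(toks) >= 2L && toks[[1L]]$type == "NAME" &&
      toks[[2L]]$type == "OP" && toks[[2L]]$value == "=") {
    ts <- tl_stream(toks[-(1:2)])
    expr <- al_parse_expr(ts)
    if (!is.null(tl_peek(ts))) al_error("trailing tokens in: ", text)
    return(list(type = "assign", target = toks[[1L]]$value, expr = expr))
  }
  ts <- tl_stream(toks)
  expr <- al_parse_expr(ts)
  if (!is.null(tl_peek(ts))) al_error("trailing tokens in: ", text)
  list(type = "expr", expr = expr)
}

# -- expression parsing ------------------------------------------------------

al_at_op <- function(ts, vals) {
  tk <- tl_peek(ts)
  !is.null(tk) && tk$type == "OP" && tk$value %in% vals
}

al_at_name <- function(ts, vals) {
  tk <- tl_peek(ts)
  !is.null(tk) && tk$type == "NAME" && tk$value %in% vals
}

al_parse_expr <- function(ts) {
  e <- al_parse_or(ts)
  if (al_at_name(ts, "if")) {
    tl_next(ts)
    cond <- al_parse_or(ts)
    if (!al_at_name(ts, "else")) al_error("conditional expression needs 'else'")
    tl_next(ts)
    alt <- al_parse_expr(ts)
    return(list(type = "ternary", test = cond, yes = e, no = alt))
  }
  e
}

al_parse_or <- function(ts) {
  e <- al_parse_and(ts)
  while (al_at_name(ts, "or")) {
    tl_next(ts)
    e <- list(type = "or", left = e, right = al_parse_and(ts))
  }
  e
}

al_parse_and <- function(ts) {
  e <- al_parse_not(ts)
  while (al_at_name(ts, "and")) {
    tl_next(ts)
    e <- list(type = "and", left = e, right = al_parse_not(ts))
  }
  e
}

al_parse_not <- function(ts) {
  if (al_at_name(ts, "not")) {
    tl_next(ts)
    return(list(type = "not", arg = al_parse_not(ts)))
  }
  al_parse_cmp(ts)
}

al_parse_cmp <- function(ts) {
  e <- al_parse_add(ts)
  while (al_at_op(ts, c("==", "!=", "<", ">", "<=", ">="))) {
    op <- tl_next(ts)$value
    e <- list(type = "cmp", op = op, left = e, right = al_parse_add(ts))
  }
  e
}

al_parse_add <- function(ts) {
  e <- al_parse_mul(ts)
  while (al_at_op(ts, c("+", "-"))) {
    op <- tl_next(ts)$value
    e <- list(type = "arith", op = op, left = e, right = al_parse_mul(ts))
  }
  e
}

al_parse_mul <- function(ts) {
  e <- al_parse_unary(ts)
  while (al_at_op(ts, c("*", "/", "%"))) {
    op <- tl_next(ts)$value
    e <- list(type = "arith", op = op, left = e, right = al_parse_unary(ts))
  }
  e
}

al_parse_unary <- function(ts) {
  if (al_at_op(ts, "-")) {
    tl_next(ts)
    return(list(type = "neg", arg = al_parse_unary(ts)))
  }
  al_parse_postfix(ts)
}

al_parse_postfix <- function(ts) {
  e <- al_parse_atom(ts)
  repeat {
    if (al_at_op(ts, ".")) {
      tl_next(ts)
      tk <- tl_next(ts)
      if (tk$type != "NAME") al_error("expected attribute name after '.'")
      e <- list(type = "attr", obj = e, name = tk$value)
    } else if (al_at_op(ts, "(")) {
      tl_next(ts)
      args <- list()
      if (!al_at_op(ts, ")")) {
        repeat {
          if (al_at_op(ts, ")")) break # tolerate trailing comma
          args[[length(args) + 1L]] <- al_parse_expr(ts)
          if (al_at_op(ts, ",")) tl_next(ts) else break
        }
      }
      if (!al_at_op(ts, ")")) al_error("expected ')' in call")
      tl_next(ts)
      e <- list(type = "call", fn = e, args = args)
    } else if (al_at_op(ts, "[")) {
      tl_next(ts)
      idx <- al_parse_expr(ts)
      if (!al_at_op(ts, "]")) al_error("expected ']'")
      tl_next(ts)
      e <- list(type = "index", obj = e, idx = idx)
    } else break
  }
  e
}

al_parse_atom <- function(ts) {
  tk <- tl_peek(ts)
  if (is.null(tk)) al_error("unexpected end of expression")
  if (tk$type == "STR") { tl_next(ts); return(list(type = "const", value = tk$value)) }
  if (tk$type == "NUM") { tl_next(ts); return(list(type = "const", value = tk$value)) }
  if (tk$type == "NAME") {
    tl_next(ts)
    if (tk$value == "None") return(list(type = "const", value = NULL))
    if (tk$value == "True") return(list(type = "const", value = TRUE))
    if (tk$value == "False") return(list(type = "const", value = FALSE))
    return(list(type = "name", name = tk$value))
  }
  if (tk$type == "OP" && tk$value == "(") {
    tl_next(ts)
    e <- al_parse_expr(ts)
    if (!al_at_op(ts, ")")) al_error("expected ')'")
    tl_next(ts)
    return(e)
  }
  if (tk$type == "OP" && tk$value == "[") {
    tl_next(ts)
    els <- list()
    if (!al_at_op(ts, "]")) {
      repeat {
        if (al_at_op(ts, "]")) break
        els[[length(els) + 1L]] <- al_parse_expr(ts)
        if (al_at_op(ts, ",")) tl_next(ts) else break
      }
    }
    if (!al_at_op(ts, "]")) al_error("expected ']'")
    tl_next(ts)
    return(list(type = "list", elements = els))
  }
  al_error("unexpected token in apply block expression")
}

# -- evaluation --------------------------------------------------------------

al_is_list <- function(x) is.list(x)

al_truthy <- function(x) {
  if (is.null(x)) return(FALSE)
  if (al_is_list(x)) return(length(x) > 0L)
  if (is.logical(x)) return(isTRUE(x))
  if (is.numeric(x)) return(x != 0)
  if (is.character(x)) return(nzchar(x))
  TRUE
}

al_as_str <- function(x) {
  if (is.null(x)) return("None")
  if (is.character(x)) return(x)
  if (is.logical(x)) return(if (isTRUE(x)) "True" else "False")
  if (is.numeric(x)) return(format(x, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  al_raise("cannot convert value to string")
}

al_eval <- function(node, env) {
  switch(node$type,
    const = node$value,
    name = {
      if (!exists(node$name, envir = env, inherits = FALSE)) {
        al_raise("name '", node$name, "' is not defined")
      }
      get(node$name, envir = env, inherits = FALSE)
    },
    list = lapply(node$elements, al_eval, env = env),
    ternary = if (al_truthy(al_eval(node$test, env)))
      al_eval(node$yes, env) else al_eval(node$no, env),
    or = {
      l <- al_eval(node$left, env)
      if (al_truthy(l)) l else al_eval(node$right, env)
    },
    and = {
      l <- al_eval(node$left, env)
      if (!al_truthy(l)) l else al_eval(node$right, env)
    },
    "not" = !al_truthy(al_eval(node$arg, env)),
    neg = {
      v <- al_eval(node$arg, env)
      if (!is.numeric(v)) al_raise("unary '-' needs a number")
      -v
    },
    cmp = al_eval_cmp(node, env),
    arith = al_eval_arith(node, env),
    index = al_eval_index(node, env),
    attr = al_raise("attribute '", node$name, "' is not callable data"),
    call = al_eval_call(node, env),
    al_error("unknown expression node")
  )
}

al_eval_cmp <- function(node, env) {
  a <- al_eval(node$left, env)
  b <- al_eval(node$right, env)
  if (is.numeric(a) && is.numeric(b)) {
    av <- a; bv <- b
  } else {
    av <- al_as_str(a); bv <- al_as_str(b)
  }
  switch(node$op,
         "==" = identical(av == bv, TRUE),
         "!=" = !identical(av == bv, TRUE),
         "<" = isTRUE(av < bv), ">" = isTRUE(av > bv),
         "<=" = isTRUE(av <= bv), ">=" = isTRUE(av >= bv))
}

al_eval_arith <- function(node, env) {
  a <- al_eval(node$left, env)
  b <- al_eval(node$right, env)
  if (node$op == "+") {
    if (al_is_list(a) && al_is_list(b)) return(c(a, b))
    if (is.character(a) || is.character(b)) {
      return(paste0(al_as_str(a), al_as_str(b)))
    }
    if (is.numeric(a) && is.numeric(b)) return(a + b)
    al_raise("unsupported operands for '+'")
  }
  if (!is.numeric(a) || !is.numeric(b)) al_raise("arithmetic needs numbers")
  switch(node$op, "-" = a - b, "*" = a * b, "/" = a / b, "%" = a %% b)
}

al_py_index <- function(len, i) {
  if (!is.numeric(i)) al_raise("index must be a number")
  i <- as.integer(i)
  if (i < 0L) i <- len + i
  if (i < 0L || i >= len) al_raise("index out of range")
  i + 1L
}

al_eval_index <- function(node, env) {
  obj <- al_eval(node$obj, env)
  i <- al_eval(node$idx, env)
  if (al_is_list(obj)) return(obj[[al_py_index(length(obj), i)]])
  if (is.character(obj)) {
    k <- al_py_index(nchar(obj), i)
    return(substr(obj, k, k))
  }
  al_raise("value is not indexable")
}

al_eval_call <- function(node, env) {
  fn <- node$fn
  args <- lapply(node$args, al_eval, env = env)
  # module functions: re.split / re.sub
  if (fn$type == "attr" && fn$obj$type == "name" && fn$obj$name == "re") {
    return(al_re_call(fn$name, args))
  }
  # builtins
  if (fn$type == "name") {
    return(al_builtin_call(fn$name, args))
  }
  # value methods
  if (fn$type == "attr") {
    recv_node <- fn$obj
    recv <- al_eval(recv_node, env)
    res <- al_method_call(recv, fn$name, args)
    if (fn$name %in% c("extend", "append") && recv_node$type == "name") {
      assign(recv_node$name, res$receiver, envir = env)
      return(NULL)
    }
    return(res$value)
  }
  al_raise("value is not callable")
}

al_re_call <- function(name, args) {
  if (name == "split") {
    if (length(args) < 2L) al_raise("re.split needs a pattern and a string")
    pat <- al_as_str(args[[1L]]); s <- al_as_str(args[[2L]])
    return(as.list(strsplit(s, pat, perl = TRUE)[[1L]]))
  }
  if (name == "sub") {
    if (length(args) < 3L) al_raise("re.sub needs pattern, replacement, string")
    return(gsub(al_as_str(args[[1L]]), al_as_str(args[[2L]]),
                al_as_str(args[[3L]]), perl = TRUE))
  }
  al_raise("unknown re function '", name, "'")
}

al_builtin_call <- function(name, args) {
  switch(name,
    len = {
      x <- args[[1L]]
      if (al_is_list(x)) length(x) else nchar(al_as_str(x))
    },
    str = al_as_str(args[[1L]]),
    int = {
      v <- suppressWarnings(as.integer(al_as_str(args[[1L]])))
      if (is.na(v)) al_raise("invalid literal for int()")
      v
    },
    float = {
      v <- suppressWarnings(as.numeric(al_as_str(args[[1L]])))
      if (is.na(v)) al_raise("invalid literal for float()")
      v
    },
    al_raise("name '", name, "' is not defined")
  )
}

al_method_call <- function(recv, name, args) {
  if (al_is_list(recv)) {
    return(switch(name,
      extend = {
        if (length(args) != 1L || !al_is_list(args[[1L]])) {
          al_raise("extend() needs a list")
        }
        list(receiver = c(recv, args[[1L]]), value = NULL)
      },
      append = list(receiver = c(recv, args), value = NULL),
      index = {
        target <- al_as_str(args[[1L]])
        hits <- which(vapply(recv, function(v)
          identical(al_as_str(v), target), logical(1)))
        if (length(hits) == 0L) al_raise("value not in list")
        list(receiver = recv, value = hits[1L] - 1L)
      },
      al_raise("list has no method '", name, "'")))
  }
  if (is.character(recv)) {
    return(list(receiver = recv, value = switch(name,
      strip = trimws(recv),
      lower = tolower(recv),
      upper = toupper(recv),
      split = {
        sep <- if (length(args)) al_as_str(args[[1L]]) else "\\s+"
        as.list(strsplit(recv, sep, fixed = length(args) > 0L)[[1L]])
      },
      replace = gsub(al_as_str(args[[1L]]), al_as_str(args[[2L]]),
                     recv, fixed = TRUE),
      startswith = startsWith(recv, al_as_str(args[[1L]])),
      endswith = endsWith(recv, al_as_str(args[[1L]])),
      join = {
        if (!al_is_list(args[[1L]])) al_raise("join() needs a list")
        paste(vapply(args[[1L]], al_as_str, character(1)), collapse = recv)
      },
      al_raise("string has no method '", name, "'"))))
  }
  al_raise("value has no methods")
}

al_exec_stmts <- function(stmts, env) {
  for (st in stmts) {
    switch(st$type,
      pass = NULL,
      assign = assign(st$target, al_eval(st$expr, env), envir = env),
      expr = { al_eval(st$expr, env) },
      "try" = {
        tryCatch(al_exec_stmts(st$body, env),
                 al_runtime_error = function(e) al_exec_stmts(st$handler, env))
      })
  }
  invisible(NULL)
}

#' Run a sandboxed apply block
#'
#' Executes the block dialect used inside JSONTL `{{ }}` sections against a
#' set of bindings and returns the value bound to `result`.
#'
#' @param code the block text (without the surrounding braces).
#' @param bindings named list of initial variables, e.g. `value`, `value1`.
#' @return the block's `result`: a scalar or a list of scalars.
#' @export
#' @examples
#' run_apply_block("result = 'ncbitax:' + value", list(value = "9606"))
run_apply_block <- function(code, bindings = list()) {
  stmts <- al_parse_program(code)
  env <- new.env(parent = emptyenv())
  for (nm in names(bindings)) assign(nm, bindings[[nm]], envir = env)
  tryCatch(al_exec_stmts(stmts, env),
           al_runtime_error = function(e) {
             stop_transform("apply block failed: ", conditionMessage(e),
                            " [block: ", trimws(code), "]")
           })
  if (!exists("result", envir = env, inherits = FALSE)) {
    stop_transform("apply block did not define 'result' [block: ",
                   trimws(code), "]")
  }
  get("result", envir = env, inherits = FALSE)
}
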