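# Transform engine -----------------------------------------------------------
#
# Executes parsed JSONTL scripts against a source tree, building a fresh
# destination tree statement by statement. Statement semantics:
#
#   constant : write the literal at the destination path
#   single   : one source path; each match (document order) is transformed
#              (optionally through apply) and written; a list result with an
#              append destination spreads one-to-many; ASSIGN NAME FROM
#              renames the final destination member per positional name match
#   columns  : N source paths aligned positionally into groups; the mandatory
#              apply runs once per group (value1..valueN, absent -> "")
#   union    : concatenated matches of all paths, each through apply, each
#              appending one destination array element
#   join     : valueK = the full match list of path K; apply picks/combines;
#              without apply all values join into one comma-separated scalar

# -- function registry -------------------------------------------------------

#' Create a plugin-function registry
#'
#' Functions are callable from JSONTL `apply` position as
#' `name("arg1", ...)`. A registered function receives `(value, args)` where
#' `value` is the matched value and `args` the literal arguments. The default
#' registry provides `toStandardDateTime`.
#'
#' @param defaults register the built-in functions?
#' @return a registry object.
#' @export
function_registry <- function(defaults = TRUE) {
  reg <- structure(list(fns = new.env(parent = emptyenv())),
                   class = "tl_registry")
  if (defaults) {
    assign("toStandardDateTime",
           function(value, args) {
             to_standard_datetime(value, if (length(args)) args[[1L]] else NULL)
           },
           envir = reg$fns)
  }
  reg
}

#' Register a plugin function
#'
#' @param registry a registry from [function_registry()].
#' @param name function name as used in scripts; must be unused.
#' @param fn `function(value, args)`.
#' @return the registry, invisibly.
#' @export
register_function <- function(registry, name, fn) {
  stopifnot(inherits(registry, "tl_registry"), is.function(fn))
  if (exists(name, envir = registry$fns, inherits = FALSE)) {
    stop_transform("function '", name, "' is already registered")
  }
  assign(name, fn, envir = registry$fns)
  invisible(registry)
}

default_registry_cache <- new.env(parent = emptyenv())

default_registry <- function() {
  if (!exists("reg", envir = default_registry_cache)) {
    assign("reg", function_registry(), envir = default_registry_cache)
  }
  get("reg", envir = default_registry_cache)
}

# -- apply dispatch ----------------------------------------------------------

tl_run_apply <- function(ap, bindings, registry) {
  if (ap$kind == "script") {
    return(run_apply_block(ap$code, bindings))
  }
  if (!exists(ap$name, envir = registry$fns, inherits = FALSE)) {
    stop_transform("apply function '", ap$name, "' is not registered")
  }
  fn <- get(ap$name, envir = registry$fns, inherits = FALSE)
  value <- if ("value" %in% names(bindings)) bindings$value else bindings
  fn(value, ap$args)
}

# scalarize a matched node for apply bindings / comparisons
tl_bind_value <- function(v) {
  if (is_tree_scalar(v)) return(v)
  v # objects/arrays pass through; blocks treat them as lists
}

# -- statement evaluation ----------------------------------------------------

dest_has_append <- function(dpath) {
  any(vapply(dpath$steps, function(s) s$kind == "append", logical(1)))
}

write_result <- function(dest, dpath, res, spread) {
  if (is.list(res) && spread) {
    for (el in res) dest <- set_value(dest, dpath, el)
    return(dest)
  }
  set_value(dest, dpath, res)
}

eval_constant <- function(stmt, dest) {
  set_value(dest, stmt$dest, stmt$literal)
}

eval_single <- function(stmt, source, dest, registry) {
  ms <- jp_match(source, stmt$sources[[1L]])
  if (length(ms) == 0L) return(dest)

  if (!is.null(stmt$assign_name_from)) {
    nms <- jp_match(source, stmt$assign_name_from)
    if (length(nms) != length(ms)) {
      stop_transform("assign name from: ", length(nms), " name match(es) for ",
                     length(ms), " value match(es)")
    }
    for (i in seq_along(ms)) {
      dpath <- stmt$dest
      last <- length(dpath$steps)
      dpath$steps[[last]]$name <- scalar_text(nms[[i]]$value)
      v <- tl_bind_value(ms[[i]]$value)
      if (!is.null(stmt$apply)) {
        v <- tl_run_apply(stmt$apply, list(value = v), registry)
      }
      dest <- set_value(dest, dpath, v)
    }
    return(dest)
  }

  spread <- dest_has_append(stmt$dest)
  if (!spread && length(ms) > 1L) {
    warning("single-path transform matched ", length(ms), " nodes for ",
            "non-array destination '", stmt$dest_text, "'; first match used",
            call. = FALSE)
    ms <- ms[1L]
  }
  for (m in ms) {
    v <- tl_bind_value(m$value)
    if (!is.null(stmt$apply)) {
      v <- tl_run_apply(stmt$apply, list(value = v), registry)
    }
    dest <- write_result(dest, stmt$dest, v, spread)
  }
  dest
}

eval_columns <- function(stmt, source, dest, registry) {
  lists <- lapply(stmt$sources, function(p) jp_match(source, p))
  G <- max(vapply(lists, length, integer(1)))
  if (G == 0L) return(dest)
  spread <- dest_has_append(stmt$dest)
  wrote <- 0L
  for (g in seq_len(G)) {
    bindings <- list()
    for (k in seq_along(lists)) {
      v <- if (g <= length(lists[[k]])) tl_bind_value(lists[[k]][[g]]$value)
           else ""
      bindings[[paste0("value", k)]] <- v
    }
    res <- tl_run_apply(stmt$apply, bindings, registry)
    if (!spread && wrote > 0L) {
      warning("multi-path transform produced several groups for non-array ",
              "destination '", stmt$dest_text, "'; first group used",
              call. = FALSE)
      break
    }
    dest <- write_result(dest, stmt$dest, res, spread)
    wrote <- wrote + 1L
  }
  dest
}

eval_union <- function(stmt, source, dest, registry) {
  vals <- list()
  for (p in stmt$sources) {
    for (m in jp_match(source, p)) {
      vals[[length(vals) + 1L]] <- tl_bind_value(m$value)
    }
  }
  if (length(vals) == 0L) return(dest)
  if (!dest_has_append(stmt$dest)) {
    stop_transform("union destination '", stmt$dest_text,
                   "' must contain an array append ([]) step")
  }
  for (v in vals) {
    res <- if (is.null(stmt$apply)) v
           else tl_run_apply(stmt$apply, list(value = v), registry)
    dest <- write_result(dest, stmt$dest, res, spread = TRUE)
  }
  dest
}

eval_join <- function(stmt, source, dest, registry) {
  bindings <- list()
  all_vals <- character(0)
  for (k in seq_along(stmt$sources)) {
    ms <- jp_match(source, stmt$sources[[k]])
    vals <- lapply(ms, function(m) tl_bind_value(m$value))
    bindings[[paste0("value", k)]] <- vals
    all_vals <- c(all_vals, vapply(vals, scalar_text, character(1)))
  }
  if (is.null(stmt$apply)) {
    if (length(all_vals) == 0L) return(dest)
    return(set_value(dest, stmt$dest, paste(all_vals, collapse = ", ")))
  }
  res <- tl_run_apply(stmt$apply, bindings, registry)
  write_result(dest, stmt$dest, res, spread = dest_has_append(stmt$dest))
}

# -- conditions --------------------------------------------------------------

like_to_regex <- function(pat) {
  # escape everything that could be a regex metacharacter, then % = any-run
  esc <- gsub("([^%A-Za-z0-9 _])", "\\\\\\1", pat)
  paste0("^", gsub("%", ".*", esc, fixed = TRUE), "$")
}

#' Evaluate a JSONTL condition against a source tree
#'
#' A comparison resolves its source path; if nothing matches the comparison
#' is false for every operator except `not exists`. `like` treats `%` as a
#' wildcard run; the ordering operators compare numerically when both sides
#' parse as numbers, lexically otherwise.
#'
#' @param cond a condition from [parse_condition()] (or condition text).
#' @param source the source document tree.
#' @return logical scalar.
#' @export
eval_condition <- function(cond, source) {
  if (is.character(cond)) cond <- parse_condition(cond)
  if (cond$type == "and") {
    for (a in cond$args) if (!eval_condition(a, source)) return(FALSE)
    return(TRUE)
  }
  if (cond$type == "or") {
    for (a in cond$args) if (eval_condition(a, source)) return(TRUE)
    return(FALSE)
  }
  ms <- jp_match(source, cond$path)
  if (cond$op == "exists") return(length(ms) > 0L)
  if (cond$op == "not_exists") return(length(ms) == 0L)
  if (length(ms) == 0L) return(FALSE)
  v <- ms[[1L]]$value
  if (!is_tree_scalar(v)) return(FALSE)
  vs <- scalar_text(v)
  if (cond$op == "like") return(grepl(like_to_regex(cond$literal), vs))
  vn <- suppressWarnings(as.numeric(vs))
  ln <- suppressWarnings(as.numeric(cond$literal))
  numeric_cmp <- !is.na(vn) && !is.na(ln)
  a <- if (numeric_cmp) vn else vs
  b <- if (numeric_cmp) ln else cond$literal
  switch(cond$op,
         eq = isTRUE(a == b), ne = !isTRUE(a == b),
         lt = isTRUE(a < b), gt = isTRUE(a > b),
         le = isTRUE(a <= b), ge = isTRUE(a >= b))
}

# -- script execution --------------------------------------------------------

#' Execute one parsed JSONTL statement
#'
#' @param stmt a `tl_statement`.
#' @param source source document tree.
#' @param dest destination tree built so far (empty object by default).
#' @param registry plugin-function registry.
#' @return the updated destination tree.
#' @export
execute_statement <- function(stmt, source, dest = tree_object(),
                              registry = default_registry()) {
  stopifnot(inherits(stmt, "tl_statement"))
  if (!is.null(stmt$condition) && !eval_condition(stmt$condition, source)) {
    return(dest)
  }
  switch(stmt$type,
         constant = eval_constant(stmt, dest),
         single = eval_single(stmt, source, dest, registry),
         columns = eval_columns(stmt, source, dest, registry),
         union = eval_union(stmt, source, dest, registry),
         join = eval_join(stmt, source, dest, registry))
}

#' Execute a JSONTL script against a source tree
#'
#' Statements run in order against the same source and a single growing
#' destination tree; statements whose condition is false are skipped. In
#' strict mode (default) a failing statement aborts the document with an
#' error naming the statement; in lenient mode it is skipped with a warning.
#'
#' @param script a `tl_script` from [parse_script()] (or script text).
#' @param source the source document tree.
#' @param dest initial destination tree (supports incremental execution).
#' @param registry plugin-function registry.
#' @param strict abort on statement failure?
#' @return the destination document tree.
#' @export
#' @examples
#' src <- json_to_tree('{"metadata":[{"name":"species","value":"rat"}]}')
#' sc <- parse_script(paste0('transform column "$.\'metadata\'[*].\'value\'" ',
#'                           'to "metadata.value" assign name from ',
#'                           '"$.\'metadata\'[*].\'name\'";'))
#' tree_to_json(execute_script(sc, src))
execute_script <- function(script, source, dest = tree_object(),
                           registry = default_registry(), strict = TRUE) {
  if (is.character(script)) script <- parse_script(script)
  stopifnot(inherits(script, "tl_script"))
  for (k in seq_along(script$statements)) {
    stmt <- script$statements[[k]]
    dest <- tryCatch(
      execute_statement(stmt, source, dest, registry),
      crucible_error = function(e) {
        msg <- paste0("statement ", k, " (", stmt$type, " -> '",
                      stmt$dest_text, "'): ", conditionMessage(e))
        if (strict) stop_transform(msg)
        warning(msg, call. = FALSE)
        dest
      })
  }
  dest
}

# -- date normalization ------------------------------------------------------

DATE_TOKEN_MAP <- c(yyyy = "%Y", MM = "%m", dd = "%d",
                    HH = "%H", mm = "%M", ss = "%S")

pattern_to_strptime <- function(pattern) {
  # longest tokens first; placeholders avoid re-substitution collisions
  out <- pattern
  marks <- c("\x01", "\x02", "\x03", "\x04", "\x05", "\x06")
  toks <- names(DATE_TOKEN_MAP)
  for (i in seq_along(toks)) out <- sub(toks[i], marks[i], out, fixed = TRUE)
  for (i in seq_along(toks)) {
    out <- gsub(marks[i], DATE_TOKEN_MAP[[toks[i]]], out, fixed = TRUE)
  }
  out
}

#' Normalize a date string to ISO 8601 date-time
#'
#' The pattern uses the letter-token dialect (`yyyy`, `MM`, `dd`, `HH`, `mm`,
#' `ss`) and is tried first; on failure (or with no pattern) flexible parsing
#' handles month names and reordered components. The output is always
#' `YYYY-MM-DDTHH:MM:SS`.
#'
#' @param raw the raw date string.
#' @param pattern optional pattern, e.g. `"yyyy-MM-dd"`.
#' @return ISO 8601 date-time string.
#' @export
#' @examples
#' to_standard_datetime("1999-01-08", "yyyy-MM-dd")
#' to_standard_datetime("Jan 8, 1999")
to_standard_datetime <- function(raw, pattern = NULL) {
  if (is.null(raw) || !is_tree_scalar(raw)) {
    stop_transform("toStandardDateTime: value is not a scalar")
  }
  raw <- trimws(as.character(raw))
  if (!nzchar(raw)) stop_transform("toStandardDateTime: empty date string")
  parsed <- NULL
  if (!is.null(pattern)) {
    p <- strptime(raw, pattern_to_strptime(pattern), tz = "UTC")
    if (!is.na(p)) parsed <- p
  }
  if (is.null(parsed)) {
    p <- suppressWarnings(lubridate::parse_date_time(
      raw,
      orders = c("Ymd HMS", "Ymd HM", "Ymd", "mdY HMS", "mdY", "dmY",
                 "dBY", "BdY", "YBd", "Ym", "Y"),
      tz = "UTC", quiet = TRUE))
    if (length(p) == 1L && !is.na(p)) parsed <- p
  }
  if (is.null(parsed)) {
    stop_transform("toStandardDateTime: cannot parse date '", raw, "'")
  }
  format(parsed, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# -- identity-script generation ----------------------------------------------

#' Generate an identity transformation script from a sample record
#'
#' Emits one `transform column` statement per scalar leaf such that executing
#' the script on the sample reproduces it (modulo object member order).
#' Arrays of scalars map through `[*]` source / `[]` destination paths;
#' arrays of objects use explicit indices so that members of one source
#' element stay together in one destination element.
#'
#' @param sample a document tree.
#' @return a `tl_script`.
#' @export
#' @examples
#' sc <- generate_identity_script(json_to_tree('{"a":{"b":"x"}}'))
#' unparse_script(sc)
generate_identity_script <- function(sample) {
  lines <- character(0)
  emit <- function(src, dst) {
    lines <<- c(lines, paste0("transform column \"", src, "\" to \"",
                              dst, "\";"))
  }
  walk <- function(node, src, dst) {
    if (is_tree_object(node)) {
      for (nm in names(node)) {
        walk(node[[nm]],
             paste0(src, ".'", nm, "'"),
             if (nzchar(dst)) paste0(dst, ".'", nm, "'") else paste0("'", nm, "'"))
      }
      return(invisible())
    }
    if (is_tree_array(node)) {
      if (length(node) == 0L) return(invisible())
      if (all(vapply(node, is_tree_scalar, logical(1)))) {
        emit(paste0(src, "[*]"), paste0(dst, "[]"))
        return(invisible())
      }
      for (i in seq_along(node)) {
        el <- node[[i]]
        if (is_tree_array(el)) {
          stop_transform("identity generation does not support arrays ",
                         "nested directly in arrays")
        }
        walk(el, paste0(src, "[", i - 1L, "]"), paste0(dst, "[", i - 1L, "]"))
      }
      return(invisible())
    }
    if (is.null(node)) return(invisible()) # nulls are dropped
    emit(src, dst)
  }
  walk(sample, "$", "")
  parse_script(paste(lines, collapse = "\n"))
}
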