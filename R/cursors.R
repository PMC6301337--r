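# Lazy cursors and fetchers --------------------------------------------------
#
# A Cursor is the lazy record-iterator contract every ingestion plan is
# composed from: has_next()/next_record()/close(). Cursors pull at most one
# record's worth of upstream input beyond their read-ahead buffer, so very
# large source dumps stream through without being materialized.

#' Lazy record cursor
#'
#' Wraps three closures into the iterator contract. `has_next()` is sticky:
#' once it returns `FALSE` it stays `FALSE`.
#'
#' @export
Cursor <- R6::R6Class("Cursor",
  public = list(
    #' @description Build a cursor from closures.
    #' @param next_fn `function()` returning the next record (a document
    #'   tree) or `NULL` when exhausted.
    #' @param close_fn optional `function()` releasing resources.
    initialize = function(next_fn, close_fn = NULL) {
      private$next_fn <- next_fn
      private$close_fn <- close_fn
    },
    #' @description Is another record available? (reads ahead one record)
    has_next = function() {
      if (private$done) return(FALSE)
      if (!is.null(private$lookahead)) return(TRUE)
      rec <- private$next_fn()
      if (is.null(rec)) {
        private$done <- TRUE
        self$close()
        return(FALSE)
      }
      private$lookahead <- list(rec)
      TRUE
    },
    #' @description The next record; error when exhausted.
    next_record = function() {
      if (!self$has_next()) stop_record("cursor is exhausted")
      rec <- private$lookahead[[1L]]
      private$lookahead <- NULL
      rec
    },
    #' @description Release underlying resources (idempotent).
    close = function() {
      if (!is.null(private$close_fn)) {
        fn <- private$close_fn
        private$close_fn <- NULL
        fn()
      }
      invisible(NULL)
    }
  ),
  private = list(next_fn = NULL, close_fn = NULL, lookahead = NULL,
                 done = FALSE)
)

#' Cursor over an in-memory record list
#'
#' @param records list of document trees.
#' @return a [Cursor].
#' @export
list_cursor <- function(records) {
  i <- 0L
  Cursor$new(function() {
    i <<- i + 1L
    if (i > length(records)) NULL else records[[i]]
  })
}

#' Drain a cursor into a list
#'
#' @param cursor a [Cursor].
#' @param n maximum number of records to take.
#' @return list of document trees.
#' @export
cursor_collect <- function(cursor, n = Inf) {
  out <- list()
  while (length(out) < n && cursor$has_next()) {
    out[[length(out) + 1L]] <- cursor$next_record()
  }
  out
}

# -- fetchers ----------------------------------------------------------------

#' Instantiate `${param}` placeholders in a URL template
#'
#' @param template URL possibly containing `${name}` placeholders.
#' @param params named list of replacement values.
#' @return the instantiated URL.
#' @export
instantiate_url <- function(template, params = list()) {
  out <- template
  for (nm in names(params)) {
    out <- gsub(paste0("${", nm, "}"), as.character(params[[nm]]),
                out, fixed = TRUE)
  }
  out
}

url_is_parameterized <- function(url) grepl("\\$\\{[^}]+\\}", url)

#' File/HTTP fetcher with a URL-keyed artifact cache
#'
#' The default implementation of the pluggable fetcher contract. Supported
#' schemes: `file://`, bare local paths, and `http`/`https` via
#' `utils::download.file`. Fetched artifacts are cached in `cache_dir` keyed
#' by a hash of the URL; re-fetching a cached URL is a cache hit and touches
#' no transport. Other transports (FTP, rsync, ...) plug in behind the same
#' contract.
#'
#' @export
Fetcher <- R6::R6Class("Fetcher",
  public = list(
    #' @field cache_dir local artifact cache directory.
    cache_dir = NULL,
    #' @field log URLs actually fetched (cache misses), in order.
    log = NULL,
    #' @description Create a fetcher.
    #' @param cache_dir artifact cache directory.
    initialize = function(cache_dir = tempfile("crucible-cache-")) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      self$cache_dir <- cache_dir
      self$log <- character(0)
    },
    #' @description Fetch a URL to a local file, through the cache.
    #' @param url the (already instantiated) URL.
    #' @return local file path.
    fetch = function(url) {
      if (url_is_parameterized(url)) {
        stop_record("URL still contains unresolved parameters: ", url)
      }
      key <- file.path(self$cache_dir,
                       paste0(digest::digest(url, algo = "sha256")))
      if (file.exists(key)) return(key)
      self$log <- c(self$log, url)
      self$retrieve(url, key)
      key
    },
    #' @description Transport implementation (override to plug in schemes).
    #' @param url source URL.
    #' @param dest local destination path.
    retrieve = function(url, dest) {
      if (startsWith(url, "file://")) {
        src <- sub("^file://", "", url)
        if (!file.exists(src)) stop_record("no such file: ", src)
        file.copy(src, dest, overwrite = TRUE)
      } else if (grepl("^https?://", url)) {
        status <- utils::download.file(url, dest, quiet = TRUE, mode = "wb")
        if (status != 0L) stop_record("download failed: ", url)
      } else if (file.exists(url)) {
        file.copy(url, dest, overwrite = TRUE)
      } else {
        stop_record("unsupported or unreachable URL: ", url)
      }
      invisible(NULL)
    }
  )
)

#' In-memory mock fetcher
#'
#' Serves byte content from a route table instead of a transport: exact URL
#' keys or `function(url)` handlers under template keys with `${param}`
#' placeholders. Implements the same contract and cache behaviour as
#' [Fetcher], so plans exercise identical code paths; `log` records cache
#' misses only, which is what endpoint-hit-count tests inspect.
#'
#' @export
MockFetcher <- R6::R6Class("MockFetcher", inherit = Fetcher,
  public = list(
    #' @field routes named list: url or template -> content or function(url).
    routes = NULL,
    #' @description Create a mock fetcher over a route set.
    #' @param routes named list of routes.
    #' @param cache_dir artifact cache directory.
    initialize = function(routes, cache_dir = tempfile("crucible-mock-")) {
      super$initialize(cache_dir)
      self$routes <- routes
    },
    #' @description Resolve a URL against the route table.
    #' @param url source URL.
    #' @param dest local destination path.
    retrieve = function(url, dest) {
      content <- private$resolve(url)
      if (is.null(content)) stop_record("mock fetcher: no route for ", url)
      writeLines(content, dest, sep = "")
      invisible(NULL)
    }
  ),
  private = list(
    resolve = function(url) {
      if (url %in% names(self$routes)) {
        r <- self$routes[[url]]
        return(if (is.function(r)) r(url) else r)
      }
      for (nm in names(self$routes)) {
        if (!grepl("${", nm, fixed = TRUE)) next
        parts <- strsplit(nm, "\\$\\{[^}]+\\}")[[1]]
        esc <- vapply(parts, function(p) gsub("([^A-Za-z0-9])", "\\\\\\1", p),
                      character(1))
        pat <- paste0("^", paste(esc, collapse = "(.+)"),
                      if (grepl("\\$\\{[^}]+\\}$", nm)) "(.+)" else "", "$")
        if (grepl(pat, url)) {
          r <- self$routes[[nm]]
          return(if (is.function(r)) r(url) else r)
        }
      }
      NULL
    }
  )
)

# -- partition cursors -------------------------------------------------------

#' Partition a raw artifact into a stream of records
#'
#' XML partitioning is incremental: the input is scanned in fixed-size chunks
#' for spans of the record element (the last name of `record_path`), and only
#' one record is materialized and parsed at a time — the first record is
#' available after reading a single chunk regardless of file size. CSV reads
#' one row per record through the header. JSON loads the document and
#' iterates the nodes matched by `record_path`.
#'
#' @param path local file path of the artifact.
#' @param format one of `"xml"`, `"json"`, `"csv"`.
#' @param record_path source path naming the repeated record element/member
#'   (e.g. `"rows.row"` or `"$.'rows'.'row'"`); ignored for CSV.
#' @param sep CSV field delimiter.
#' @param chunk_size bytes per read for streaming XML.
#' @return a [Cursor]; for XML it carries a `bytes_read()` method accessible
#'   via `attr(cursor, "bytes_read")`.
#' @export
partition_cursor <- function(path, format = c("xml", "json", "csv"),
                             record_path = NULL, sep = ",",
                             chunk_size = 32768L) {
  format <- match.arg(format)
  switch(format,
         xml = xml_partition_cursor(path, record_path, chunk_size),
         json = json_partition_cursor(path, record_path),
         csv = csv_partition_cursor(path, sep))
}

record_tag_of <- function(record_path) {
  if (is.null(record_path)) stop_parse("record path is required")
  if (inherits(record_path, "jp_source_path")) {
    steps <- record_path$steps
    if (length(steps) == 0L) stop_parse("record path must name an element")
    return(steps[[length(steps)]]$name)
  }
  txt <- trimws(record_path)
  if (startsWith(txt, "$")) {
    return(record_tag_of(parse_source_path(txt)))
  }
  parts <- strsplit(txt, ".", fixed = TRUE)[[1]]
  parts[length(parts)]
}

xml_partition_cursor <- function(path, record_path, chunk_size = 32768L) {
  tag <- record_tag_of(record_path)
  con <- file(path, "rb")
  buf <- ""
  eof <- FALSE
  bytes <- 0L
  tag_re <- gsub("([^A-Za-z0-9_])", "\\\\\\1", tag)
  open_re <- paste0("<", tag_re, "(?=[\\s/>])")
  close_re <- paste0("</", tag_re, "\\s*>")

  read_more <- function() {
    if (eof) return(FALSE)
    chunk <- readChar(con, chunk_size, useBytes = TRUE)
    if (length(chunk) == 0L || nchar(chunk, type = "bytes") == 0L) {
      eof <<- TRUE
      return(FALSE)
    }
    bytes <<- bytes + nchar(chunk, type = "bytes")
    buf <<- paste0(buf, chunk)
    TRUE
  }

  next_span <- function() {
    repeat {
      m <- regexpr(open_re, buf, perl = TRUE)
      if (m > 0) break
      # keep a tail in case a start tag straddles the chunk boundary
      keep <- max(1L, nchar(buf) - (nchar(tag) + 2L))
      buf <<- substr(buf, keep, nchar(buf))
      if (!read_more()) return(NULL)
    }
    start <- as.integer(m)
    buf <<- substr(buf, start, nchar(buf))
    # scan forward over tags of this name, tracking depth
    pos <- 1L
    depth <- 0L
    repeat {
      rest <- substr(buf, pos, nchar(buf))
      mo <- regexpr(open_re, rest, perl = TRUE)
      mc <- regexpr(close_re, rest, perl = TRUE)
      if (mo > 0 && (mc <= 0 || mo < mc)) {
        tag_start <- pos + as.integer(mo) - 1L
        gt <- find_tag_end(tag_start)
        if (is.null(gt)) { if (!read_more()) return(flush_bad()); next }
        if (substr(buf, gt - 1L, gt - 1L) == "/") {
          if (depth == 0L) return(cut_span(tag_start, gt))
        } else {
          depth <- depth + 1L
        }
        pos <- gt + 1L
      } else if (mc > 0) {
        cl_start <- pos + as.integer(mc) - 1L
        cl_end <- cl_start + attr(mc, "match.length") - 1L
        depth <- depth - 1L
        if (depth == 0L) return(cut_span(1L, cl_end))
        pos <- cl_end + 1L
      } else {
        if (!read_more()) return(flush_bad())
      }
    }
  }

  find_tag_end <- function(from) {
    k <- regexpr(">", substr(buf, from, nchar(buf)), fixed = TRUE)
    if (k <= 0) return(NULL)
    from + as.integer(k) - 1L
  }

  cut_span <- function(from, to) {
    span <- substr(buf, from, to)
    buf <<- substr(buf, to + 1L, nchar(buf))
    span
  }

  flush_bad <- function() {
    stop_parse("malformed XML stream: unterminated <", tag, "> record")
  }

  cur <- Cursor$new(
    next_fn = function() {
      span <- next_span()
      if (is.null(span)) return(NULL)
      xml_to_tree(span)
    },
    close_fn = function() try(close(con), silent = TRUE)
  )
  attr(cur, "bytes_read") <- function() bytes
  attr(cur, "total_bytes") <- file.size(path)
  cur
}

csv_partition_cursor <- function(path, sep = ",") {
  con <- file(path, "r")
  header <- NULL
  Cursor$new(
    next_fn = function() {
      if (is.null(header)) {
        h <- utils::read.csv(con, nrows = 1, header = FALSE, sep = sep,
                             colClasses = "character")
        if (nrow(h) == 0L) return(NULL)
        header <<- as.character(h[1L, ])
      }
      row <- tryCatch(
        utils::read.csv(con, nrows = 1, header = FALSE, sep = sep,
                        colClasses = "character"),
        error = function(e) NULL)
      if (is.null(row) || nrow(row) == 0L) return(NULL)
      csv_row_to_tree(header, as.character(row[1L, ]))
    },
    close_fn = function() try(close(con), silent = TRUE)
  )
}

json_partition_cursor <- function(path, record_path) {
  tree <- json_to_tree(path)
  recs <- if (is.null(record_path) || identical(trimws(record_path), "$")) {
    if (is_tree_array(tree)) tree else list(tree)
  } else {
    p <- if (inherits(record_path, "jp_source_path")) record_path
         else parse_source_path(
           if (startsWith(trimws(record_path), "$")) record_path
           else paste0("$.", gsub("([^.]+)", "'\\1'", record_path)))
    ms <- jp_match(tree, p)
    vals <- list()
    for (m in ms) {
      v <- m$value
      if (is_tree_array(v)) vals <- c(vals, v) else vals <- c(vals, list(v))
    }
    vals
  }
  list_cursor(recs)
}

# -- join cursor -------------------------------------------------------------

resolve_key <- function(record, key_path) {
  ms <- jp_match(record, key_path)
  if (length(ms) == 0L) return(NULL)
  if (length(ms) > 1L) {
    stop_record("join key path matches ", length(ms), " nodes")
  }
  v <- ms[[1L]]$value
  if (!is_tree_scalar(v)) stop_record("join key does not resolve to a scalar")
  scalar_text(v)
}

#' Streaming inner-join cursor
#'
#' Joins a left cursor against a right side on scalar key paths. A static
#' right side is drained once into a key index on first use; a parameterized
#' right side (`right_fn`) is fetched on demand once per distinct left key
#' (the fetcher cache deduplicates repeated keys). The joined record is the
#' left tree with the matching right tree nested under `right_alias`.
#'
#' @param left a [Cursor].
#' @param left_key,right_key source paths resolving to scalar join keys.
#' @param right_alias member name for the nested right record.
#' @param right_cursor_fn `function()` returning a fresh cursor over the
#'   static right side (used to build the index), or `NULL`.
#' @param right_fn `function(key)` returning the list of right records for a
#'   key (parameterized side), or `NULL`.
#' @param on_record_error `function(condition)` called for per-record errors
#'   (the record is skipped).
#' @return a [Cursor] over joined records.
#' @export
join_cursor <- function(left, left_key, right_key, right_alias,
                        right_cursor_fn = NULL, right_fn = NULL,
                        on_record_error = NULL) {
  if (is.character(left_key)) left_key <- parse_source_path(left_key)
  if (is.character(right_key)) right_key <- parse_source_path(right_key)
  stopifnot(xor(is.null(right_cursor_fn), is.null(right_fn)))
  index <- NULL
  pending <- list()

  build_index <- function() {
    index <<- new.env(parent = emptyenv())
    rc <- right_cursor_fn()
    while (rc$has_next()) {
      r <- rc$next_record()
      k <- tryCatch(resolve_key(r, right_key), crucible_error = function(e) {
        if (!is.null(on_record_error)) on_record_error(e)
        NULL
      })
      if (is.null(k)) next
      cur <- if (exists(k, envir = index, inherits = FALSE)) {
        get(k, envir = index, inherits = FALSE)
      } else list()
      assign(k, c(cur, list(r)), envir = index)
    }
    rc$close()
  }

  rights_for <- function(key) {
    if (!is.null(right_fn)) {
      recs <- right_fn(key)
      keep <- list()
      for (r in recs) {
        k <- tryCatch(resolve_key(r, right_key),
                      crucible_error = function(e) NULL)
        # verify the fetched record really carries the key (inner join)
        if (!is.null(k) && identical(k, key)) keep[[length(keep) + 1L]] <- r
      }
      return(keep)
    }
    if (is.null(index)) build_index()
    if (exists(key, envir = index, inherits = FALSE)) {
      get(key, envir = index, inherits = FALSE)
    } else list()
  }

  Cursor$new(
    next_fn = function() {
      repeat {
        if (length(pending)) {
          out <- pending[[1L]]
          pending <<- pending[-1L]
          return(out)
        }
        if (!left$has_next()) return(NULL)
        l <- left$next_record()
        k <- tryCatch(resolve_key(l, left_key), crucible_error = function(e) {
          if (!is.null(on_record_error)) on_record_error(e)
          NULL
        })
        if (is.null(k)) next
        for (r in rights_for(k)) {
          merged <- l
          merged[[right_alias]] <- r
          pending[[length(pending) + 1L]] <- merged
        }
      }
    },
    close_fn = function() left$close()
  )
}
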