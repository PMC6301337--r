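# Ingestion DSL --------------------------------------------------------------
#
# Declarative scripts describing how raw data is retrieved, partitioned into
# records and joined before entering the pipeline. Statements form a pipeline
# of low-level operations over aliased artifacts:
#
#   SET name = "value";
#   DOWNLOAD "<url>" TO alias FORMAT xml|json|csv;
#   EXTRACT alias FROM bundleAlias NAME "<glob>";
#   PARTITION alias = srcAlias ON "<recordPath>";
#   JOIN alias = leftAlias TO rightAlias ON "<leftPath>" = "<rightPath>";
#   INGEST alias;
#
# Keywords are case-insensitive; aliases must be defined before use; the
# script ends with exactly one INGEST statement. A DOWNLOAD whose URL keeps
# `${param}` placeholders unresolved after SET substitution is a
# *parameterized* artifact: it is fetched on demand, once per distinct join
# key arriving from the left side.

IG_KEYWORDS <- c("set", "download", "to", "format", "extract", "from",
                 "name", "partition", "on", "join", "ingest")

#' Parse an ingestion DSL script
#'
#' @param text script text, or a path to a `.igl` file.
#' @return an `ig_script` (statements + alias table).
#' @export
parse_ingest_script <- function(text) {
  if (length(text) == 1L && !grepl("[;\"]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  ts <- tl_stream(tl_lex(text, keywords = IG_KEYWORDS), text)
  stmts <- list()
  aliases <- character(0)
  need_alias <- function(a) {
    if (!a %in% aliases) tl_error(ts, "alias '", a, "' used before definition")
  }
  def_alias <- function(a) {
    if (a %in% aliases) tl_error(ts, "alias '", a, "' defined twice")
    aliases <<- c(aliases, a)
  }
  ingest_seen <- FALSE
  while (!is.null(tl_peek(ts))) {
    if (ingest_seen) tl_error(ts, "INGEST must be the last statement")
    tk <- tl_next(ts)
    if (tk$type != "KW") tl_error(ts, "expected a statement keyword")
    st <- switch(tk$value,
      set = {
        nm <- tl_expect(ts, "NAME")$value
        tl_expect(ts, "OP", "=")
        val <- tl_expect(ts, "STRING")$value
        list(type = "set", name = nm, value = val)
      },
      download = {
        url <- tl_expect(ts, "STRING")$value
        tl_expect(ts, "KW", "to")
        alias <- tl_expect(ts, "NAME")$value
        tl_expect(ts, "KW", "format")
        fmt <- tolower(ig_name_or_kw(ts))
        if (!fmt %in% c("xml", "json", "csv")) {
          tl_error(ts, "unknown format '", fmt, "'")
        }
        def_alias(alias)
        list(type = "download", url = url, alias = alias, format = fmt)
      },
      extract = {
        alias <- tl_expect(ts, "NAME")$value
        tl_expect(ts, "KW", "from")
        bundle <- tl_expect(ts, "NAME")$value
        need_alias(bundle)
        tl_expect(ts, "KW", "name")
        glob <- tl_expect(ts, "STRING")$value
        def_alias(alias)
        list(type = "extract", alias = alias, bundle = bundle, glob = glob)
      },
      partition = {
        alias <- tl_expect(ts, "NAME")$value
        tl_expect(ts, "OP", "=")
        src <- tl_expect(ts, "NAME")$value
        need_alias(src)
        tl_expect(ts, "KW", "on")
        rp <- tl_expect(ts, "STRING")$value
        def_alias(alias)
        list(type = "partition", alias = alias, src = src, record_path = rp)
      },
      join = {
        alias <- tl_expect(ts, "NAME")$value
        tl_expect(ts, "OP", "=")
        left <- tl_expect(ts, "NAME")$value
        need_alias(left)
        tl_expect(ts, "KW", "to")
        right <- tl_expect(ts, "NAME")$value
        need_alias(right)
        tl_expect(ts, "KW", "on")
        lk <- tl_expect(ts, "STRING")$value
        tl_expect(ts, "OP", "=")
        rk <- tl_expect(ts, "STRING")$value
        def_alias(alias)
        list(type = "join", alias = alias, left = left, right = right,
             left_key = lk, right_key = rk)
      },
      ingest = {
        alias <- tl_expect(ts, "NAME")$value
        need_alias(alias)
        ingest_seen <- TRUE
        list(type = "ingest", alias = alias)
      },
      tl_error(ts, "unknown statement keyword '", tk$value, "'"))
    tl_expect(ts, "PUNCT", ";")
    stmts[[length(stmts) + 1L]] <- st
  }
  if (!ingest_seen) {
    stop_parse("ingestion script must end with an INGEST statement")
  }
  structure(list(statements = stmts, aliases = aliases), class = "ig_script")
}

# FORMAT values collide with no keywords, but accept either token type
ig_name_or_kw <- function(ts) {
  tk <- tl_next(ts)
  if (!tk$type %in% c("NAME", "KW")) tl_error(ts, "expected a format name")
  tk$value
}

#' @export
print.ig_script <- function(x, ...) {
  cat("<ingestion script: ", length(x$statements), " statement(s); ingests '",
      x$statements[[length(x$statements)]]$alias, "'>\n", sep = "")
  invisible(x)
}

# -- planning ----------------------------------------------------------------

#' Compile an ingestion script into a lazy record cursor
#'
#' Converts the declarative statements into a pipeline of fetch, extract,
#' partition and join cursors; the returned cursor streams the records named
#' by the INGEST statement. Non-parameterized join right sides are indexed by
#' key on first use; parameterized right sides are fetched per distinct left
#' key through the fetcher cache.
#'
#' @param script an `ig_script` (or script text).
#' @param params named list overriding/adding SET parameters.
#' @param fetcher a [Fetcher] (or [MockFetcher]).
#' @param on_record_error callback for skipped records.
#' @return a [Cursor].
#' @export
plan_ingestion <- function(script, params = list(),
                           fetcher = Fetcher$new(),
                           on_record_error = NULL) {
  if (is.character(script)) script <- parse_ingest_script(script)
  stopifnot(inherits(script, "ig_script"))

  set_params <- list()
  defs <- list()
  for (st in script$statements) {
    if (st$type == "set") set_params[[st$name]] <- st$value
    else if (st$type != "ingest" && !is.null(st$alias)) defs[[st$alias]] <- st
  }
  for (nm in names(params)) set_params[[nm]] <- params[[nm]]

  resolved_url <- function(st) instantiate_url(st$url, set_params)

  artifact_path <- function(alias) {
    st <- defs[[alias]]
    if (st$type == "download") return(fetcher$fetch(resolved_url(st)))
    if (st$type == "extract") {
      bundle <- artifact_path(st$bundle)
      exdir <- file.path(fetcher$cache_dir, paste0(st$alias, "-extract"))
      if (!dir.exists(exdir)) {
        dir.create(exdir, recursive = TRUE)
        utils::untar(bundle, exdir = exdir)
      }
      hits <- list.files(exdir, pattern = utils::glob2rx(st$glob),
                         recursive = TRUE, full.names = TRUE)
      if (length(hits) == 0L) {
        stop_record("no bundle member matches '", st$glob, "'")
      }
      return(hits[[1L]])
    }
    stop_parse("alias '", alias, "' is not a file artifact")
  }

  artifact_format <- function(alias) {
    st <- defs[[alias]]
    if (st$type == "download") return(st$format)
    if (st$type == "extract") return(defs[[st$bundle]]$format)
    stop_parse("alias '", alias, "' has no format")
  }

  is_parameterized <- function(alias) {
    st <- defs[[alias]]
    base <- switch(st$type,
                   download = st,
                   extract = defs[[st$bundle]],
                   partition = return(is_parameterized(st$src)),
                   return(FALSE))
    url_is_parameterized(instantiate_url(base$url, set_params))
  }

  # records of an alias for one join key (parameterized side)
  records_for_key <- function(alias, key) {
    st <- defs[[alias]]
    if (st$type == "partition") {
      base <- defs[[st$src]]
      url <- instantiate_all(resolved_url(base), key)
      path <- fetcher$fetch(url)
      return(cursor_collect(partition_cursor(path, base$format,
                                             st$record_path)))
    }
    url <- instantiate_all(resolved_url(st), key)
    path <- fetcher$fetch(url)
    list(whole_artifact_record(path, st$format))
  }

  cursor_for <- function(alias) {
    st <- defs[[alias]]
    switch(st$type,
      partition = {
        src_path <- artifact_path(st$src)
        partition_cursor(src_path, artifact_format(st$src), st$record_path)
      },
      download = ,
      extract = {
        path <- artifact_path(alias)
        list_cursor(list(whole_artifact_record(path, artifact_format(alias))))
      },
      join = {
        left <- cursor_for(st$left)
        if (is_parameterized(st$right)) {
          join_cursor(left, st$left_key, st$right_key,
                      right_alias = st$right,
                      right_fn = function(key) records_for_key(st$right, key),
                      on_record_error = on_record_error)
        } else {
          join_cursor(left, st$left_key, st$right_key,
                      right_alias = st$right,
                      right_cursor_fn = function() cursor_for(st$right),
                      on_record_error = on_record_error)
        }
      },
      stop_parse("cannot build a cursor for alias '", alias, "'"))
  }

  final <- script$statements[[length(script$statements)]]$alias
  cursor_for(final)
}

instantiate_all <- function(url, value) {
  gsub("\\$\\{[^}]+\\}", value, url)
}

whole_artifact_record <- function(path, format) {
  switch(format,
         xml = xml_to_tree(paste(readLines(path, warn = FALSE),
                                 collapse = "\n")),
         json = json_to_tree(path),
         csv = {
           cur <- csv_partition_cursor(path)
           recs <- cursor_collect(cur)
           if (length(recs) == 1L) recs[[1L]] else recs
         })
}

# -- running a source --------------------------------------------------------

descriptor_cursor <- function(descriptor, fetcher, params = list(),
                              on_record_error = NULL) {
  p <- descriptor$params
  fetch_one <- function(url) fetcher$fetch(instantiate_url(url, params))
  switch(descriptor$ingest_method,
    "dsl" = {
      script <- if (!is.null(p$script)) p$script else p$scriptRef
      plan_ingestion(script, params = params, fetcher = fetcher,
                     on_record_error = on_record_error)
    },
    "web-service" = ,
    "xml" = partition_cursor(fetch_one(p$url),
                             format = if (!is.null(p$format)) p$format
                                      else "xml",
                             record_path = p$recordPath),
    "csv" = partition_cursor(fetch_one(p$url), format = "csv",
                             sep = if (!is.null(p$delimiter)) p$delimiter
                                   else ","),
    "two-stage-web-service" = {
      listing <- partition_cursor(fetch_one(p$listUrl),
                                  format = if (!is.null(p$format)) p$format
                                           else "xml",
                                  record_path = p$recordPath)
      id_path <- parse_source_path(p$idPath)
      Cursor$new(next_fn = function() {
        repeat {
          if (!listing$has_next()) return(NULL)
          entry <- listing$next_record()
          ms <- jp_match(entry, id_path)
          if (length(ms) == 0L || !is_tree_scalar(ms[[1L]]$value)) next
          id <- scalar_text(ms[[1L]]$value)
          url <- instantiate_all(instantiate_url(p$detailUrlTemplate, params),
                                 id)
          path <- fetcher$fetch(url)
          fmt <- if (!is.null(p$detailFormat)) p$detailFormat else "xml"
          return(whole_artifact_record(path, fmt))
        }
      }, close_fn = function() listing$close())
    },
    "file" = {
      if (dir.exists(p$path)) {
        files <- sort(list.files(p$path, full.names = TRUE))
        i <- 0L
        Cursor$new(next_fn = function() {
          i <<- i + 1L
          if (i > length(files)) return(NULL)
          whole_artifact_record(files[[i]], p$format)
        })
      } else if (!is.null(p$recordPath)) {
        partition_cursor(p$path, p$format, p$recordPath)
      } else {
        list_cursor(list(whole_artifact_record(p$path, p$format)))
      }
    })
}

#' Harvest a source into a document store
#'
#' Drains the source's planned cursor; for every record the primary key is
#' extracted, the content checksum computed, and the store consulted: an
#' unseen (source, key) is stored as new, an identical checksum is counted
#' as a duplicate and skipped, a changed checksum replaces the stored record
#' (updated). Records enter with the pipeline start status.
#'
#' @param descriptor a `source_descriptor`.
#' @param store a document store ([MemoryStore]/[FileStore]).
#' @param fetcher a [Fetcher].
#' @param params extra `${param}` substitutions.
#' @param start_status status label assigned to stored records.
#' @return an ingestion report:
#'   `list(seen, new, updated, duplicate, errors, doc_ids)`.
#' @export
run_ingestion <- function(descriptor, store, fetcher = Fetcher$new(),
                          params = list(), start_status = "new") {
  stopifnot(inherits(descriptor, "source_descriptor"))
  rep <- list(seen = 0L, new = 0L, updated = 0L, duplicate = 0L,
              errors = 0L, doc_ids = character(0))
  on_err <- function(e) rep$errors <<- rep$errors + 1L
  cur <- descriptor_cursor(descriptor, fetcher, params,
                           on_record_error = on_err)
  pk_path <- parse_source_path(descriptor$params$primaryKeyPath)
  while (cur$has_next()) {
    rec <- tryCatch(cur$next_record(), crucible_error = function(e) {
      rep$errors <<- rep$errors + 1L
      NULL
    })
    if (is.null(rec)) next
    rep$seen <- rep$seen + 1L
    ok <- tryCatch({
      ms <- jp_match(rec, pk_path)
      if (length(ms) == 0L || !is_tree_scalar(ms[[1L]]$value)) {
        stop_record("record has no primary key at ",
                    descriptor$params$primaryKeyPath)
      }
      key <- scalar_text(ms[[1L]]$value)
      existing <- store$find_by_source_key(descriptor$source_id, key)
      if (is.null(existing)) {
        w <- document_wrapper(descriptor$source_id, key, rec,
                              status = start_status)
        store$put(w)
        rep$new <- rep$new + 1L
        rep$doc_ids <- c(rep$doc_ids, w$doc_id)
      } else if (identical(existing$checksum, tree_checksum(rec))) {
        rep$duplicate <- rep$duplicate + 1L
      } else {
        w <- document_wrapper(descriptor$source_id, key, rec,
                              status = start_status,
                              doc_id = existing$doc_id)
        store$put(w)
        rep$updated <- rep$updated + 1L
        rep$doc_ids <- c(rep$doc_ids, w$doc_id)
      }
      TRUE
    }, crucible_error = function(e) {
      rep$errors <<- rep$errors + 1L
      FALSE
    })
    if (!ok) next
  }
  cur$close()
  rep
}
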