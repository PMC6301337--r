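# Document wrappers, source descriptors and document stores ------------------

#' Create a document wrapper
#'
#' The envelope carried through the pipeline: original record, transformed
#' record (once produced), source identity, primary key, content checksum,
#' current status and a status history. The checksum is order-insensitive
#' over object members, so re-harvested records compare stably.
#'
#' @param source_id source identifier string.
#' @param primary_key the record's key within its source.
#' @param original the original record (document tree).
#' @param status initial status label.
#' @param doc_id unique document id; defaults to `source_id:primary_key`.
#' @param time timestamp for the first history entry.
#' @return a `doc_wrapper`.
#' @export
document_wrapper <- function(source_id, primary_key, original,
                             status = "new",
                             doc_id = paste0(source_id, ":", primary_key),
                             time = Sys.time()) {
  structure(list(
    doc_id = doc_id,
    source_id = source_id,
    primary_key = as.character(primary_key),
    checksum = tree_checksum(original),
    status = status,
    original_record = original,
    transformed_record = NULL,
    history = list(list(status = status,
                        time = format(time, "%Y-%m-%dT%H:%M:%OS3Z",
                                      tz = "UTC")))
  ), class = "doc_wrapper")
}

#' Advance a wrapper to a new status
#'
#' Appends a history entry; the wrapper's status always equals the last
#' history entry.
#'
#' @param wrapper a `doc_wrapper`.
#' @param status new status label.
#' @param time timestamp.
#' @return the updated wrapper.
#' @export
wrapper_set_status <- function(wrapper, status, time = Sys.time()) {
  wrapper$status <- status
  wrapper$history[[length(wrapper$history) + 1L]] <-
    list(status = status,
         time = format(time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
  wrapper
}

#' @export
print.doc_wrapper <- function(x, ...) {
  cat("<doc_wrapper ", x$doc_id, "> status=", x$status,
      " checksum=", substr(x$checksum, 1, 12), "... history=",
      paste(vapply(x$history, `[[`, character(1), "status"),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

wrapper_to_tree <- function(w) {
  out <- tree_object(
    docId = w$doc_id,
    sourceId = w$source_id,
    primaryKey = w$primary_key,
    checksum = w$checksum,
    status = w$status,
    originalRecord = w$original_record
  )
  if (!is.null(w$transformed_record)) {
    out[["transformedRecord"]] <- w$transformed_record
  }
  out[["history"]] <- lapply(w$history, function(h) {
    tree_object(status = h$status, time = h$time)
  })
  out
}

tree_to_wrapper <- function(t) {
  w <- structure(list(
    doc_id = t[["docId"]],
    source_id = t[["sourceId"]],
    primary_key = t[["primaryKey"]],
    checksum = t[["checksum"]],
    status = t[["status"]],
    original_record = t[["originalRecord"]],
    transformed_record = t[["transformedRecord"]],
    history = lapply(t[["history"]], function(h) {
      list(status = h[["status"]], time = h[["time"]])
    })
  ), class = "doc_wrapper")
  w
}

# -- source descriptors ------------------------------------------------------

DESCRIPTOR_REQUIRED <- list(
  "dsl" = c("script", "primaryKeyPath"),
  "web-service" = c("url", "recordPath", "primaryKeyPath"),
  "two-stage-web-service" = c("listUrl", "recordPath", "idPath",
                              "detailUrlTemplate", "primaryKeyPath"),
  "csv" = c("url", "primaryKeyPath"),
  "xml" = c("url", "recordPath", "primaryKeyPath"),
  "file" = c("path", "format", "primaryKeyPath")
)

#' Create or validate a harvest source descriptor
#'
#' @param source_id source identifier.
#' @param name human-readable source name.
#' @param ingest_method one of `dsl`, `web-service`, `two-stage-web-service`,
#'   `csv`, `xml`, `file`.
#' @param params named character list; each method's required parameters are
#'   validated (e.g. `url`, `recordPath`, `primaryKeyPath`).
#' @param transform_script optional path to (or inline text of) a JSONTL
#'   script applied downstream.
#' @return a `source_descriptor`.
#' @export
source_descriptor <- function(source_id, name, ingest_method, params,
                              transform_script = NULL) {
  if (!ingest_method %in% names(DESCRIPTOR_REQUIRED)) {
    stop_parse("unknown ingest method '", ingest_method, "'")
  }
  missing <- setdiff(DESCRIPTOR_REQUIRED[[ingest_method]], names(params))
  # a dsl script may be given inline or as a file reference
  if (ingest_method == "dsl" && "scriptRef" %in% names(params)) {
    missing <- setdiff(missing, "script")
  }
  if (length(missing)) {
    stop_parse("descriptor for '", source_id, "' (", ingest_method,
               ") is missing required param(s): ",
               paste(missing, collapse = ", "))
  }
  structure(list(source_id = source_id, name = name,
                 ingest_method = ingest_method, params = params,
                 transform_script = transform_script),
            class = "source_descriptor")
}

#' Read a harvest descriptor from a JSON file
#'
#' @param path JSON file with fields `sourceId`, `name`, `ingestMethod`,
#'   `params` and optional `transformScriptRef`.
#' @return a validated `source_descriptor`.
#' @export
read_source_descriptor <- function(path) {
  t <- json_to_tree(path)
  source_descriptor(t[["sourceId"]], t[["name"]], t[["ingestMethod"]],
                    t[["params"]], t[["transformScriptRef"]])
}

# -- document stores ---------------------------------------------------------

#' In-memory document store
#'
#' The reference backend of the pluggable document-store contract:
#' `put`/`get`/`update_status`/`find_by_source_key`/`select`. Suitable for
#' tests and single-process runs; `FileStore` provides the same contract
#' persisted as one JSON file per document.
#'
#' @export
MemoryStore <- R6::R6Class("MemoryStore",
  public = list(
    #' @description Create an empty store.
    initialize = function() {
      private$docs <- new.env(parent = emptyenv())
    },
    #' @description Insert or overwrite a wrapper.
    #' @param wrapper a `doc_wrapper`.
    put = function(wrapper) {
      stopifnot(inherits(wrapper, "doc_wrapper"))
      assign(wrapper$doc_id, wrapper, envir = private$docs)
      invisible(wrapper$doc_id)
    },
    #' @description Fetch a wrapper by id (NULL if absent).
    #' @param doc_id document id.
    get = function(doc_id) {
      if (!exists(doc_id, envir = private$docs, inherits = FALSE)) return(NULL)
      base::get(doc_id, envir = private$docs, inherits = FALSE)
    },
    #' @description Append a status to a stored wrapper's history.
    #' @param doc_id document id.
    #' @param status new status label.
    update_status = function(doc_id, status) {
      w <- self$get(doc_id)
      if (is.null(w)) stop_record("no such document: ", doc_id)
      self$put(wrapper_set_status(w, status))
    },
    #' @description Find by (source, primary key).
    #' @param source_id,primary_key identity pair.
    find_by_source_key = function(source_id, primary_key) {
      for (id in self$ids()) {
        w <- self$get(id)
        if (identical(w$source_id, source_id) &&
            identical(w$primary_key, as.character(primary_key))) return(w)
      }
      NULL
    },
    #' @description All document ids, sorted.
    ids = function() sort(ls(envir = private$docs)),
    #' @description Number of stored documents.
    count = function() length(ls(envir = private$docs)),
    #' @description Wrappers filtered by source and/or status, ordered by id.
    #' @param source_id,status optional filters.
    select = function(source_id = NULL, status = NULL) {
      out <- list()
      for (id in self$ids()) {
        w <- self$get(id)
        if (!is.null(source_id) && !identical(w$source_id, source_id)) next
        if (!is.null(status) && !identical(w$status, status)) next
        out[[length(out) + 1L]] <- w
      }
      out
    }
  ),
  private = list(docs = NULL)
)

#' File-backed document store
#'
#' Same contract as [MemoryStore]; persists each wrapper as one JSON file
#' named by a sanitized document id inside `dir`.
#'
#' @export
FileStore <- R6::R6Class("FileStore",
  public = list(
    #' @field dir storage directory.
    dir = NULL,
    #' @description Open (creating if needed) a directory-backed store.
    #' @param dir storage directory.
    initialize = function(dir) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      self$dir <- dir
    },
    #' @description Insert or overwrite a wrapper.
    #' @param wrapper a `doc_wrapper`.
    put = function(wrapper) {
      stopifnot(inherits(wrapper, "doc_wrapper"))
      writeLines(tree_to_json(wrapper_to_tree(wrapper)),
                 file.path(self$dir, private$fname(wrapper$doc_id)))
      invisible(wrapper$doc_id)
    },
    #' @description Fetch a wrapper by id (NULL if absent).
    #' @param doc_id document id.
    get = function(doc_id) {
      f <- file.path(self$dir, private$fname(doc_id))
      if (!file.exists(f)) return(NULL)
      tree_to_wrapper(json_to_tree(f))
    },
    #' @description Append a status to a stored wrapper's history.
    #' @param doc_id document id.
    #' @param status new status label.
    update_status = function(doc_id, status) {
      w <- self$get(doc_id)
      if (is.null(w)) stop_record("no such document: ", doc_id)
      self$put(wrapper_set_status(w, status))
    },
    #' @description Find by (source, primary key).
    #' @param source_id,primary_key identity pair.
    find_by_source_key = function(source_id, primary_key) {
      for (id in self$ids()) {
        w <- self$get(id)
        if (identical(w$source_id, source_id) &&
            identical(w$primary_key, as.character(primary_key))) return(w)
      }
      NULL
    },
    #' @description All document ids, sorted.
    ids = function() {
      fs <- sort(list.files(self$dir, pattern = "\\.json$"))
      vapply(fs, function(f) {
        tree <- json_to_tree(file.path(self$dir, f))
        tree[["docId"]]
      }, character(1), USE.NAMES = FALSE)
    },
    #' @description Number of stored documents.
    count = function() length(list.files(self$dir, pattern = "\\.json$")),
    #' @description Wrappers filtered by source and/or status, ordered by id.
    #' @param source_id,status optional filters.
    select = function(source_id = NULL, status = NULL) {
      out <- list()
      for (id in self$ids()) {
        w <- self$get(id)
        if (!is.null(source_id) && !identical(w$source_id, source_id)) next
        if (!is.null(status) && !identical(w$status, status)) next
        out[[length(out) + 1L]] <- w
      }
      out
    }
  ),
  private = list(
    fname = function(doc_id) {
      paste0(gsub("[^A-Za-z0-9._-]", "_", doc_id), ".json")
    }
  )
)
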