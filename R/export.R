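# Export ---------------------------------------------------------------------
#
# Terminal pipeline step: transformed documents leave the store as JSON
# lines, search-engine bulk actions, or one file per document. Output order
# is fixed (sorted by document id) so re-export of an unchanged store is
# byte-identical.

select_docs <- function(store, source_id = NULL, status = NULL) {
  store$select(source_id = source_id, status = status)
}

export_payload <- function(w) {
  out <- tree_object(`_id` = w$doc_id, sourceId = w$source_id,
                     primaryKey = w$primary_key)
  out[["data"]] <- if (!is.null(w$transformed_record)) w$transformed_record
                   else w$original_record
  out
}

#' Export documents as JSON lines
#'
#' One JSON object per line: the transformed record under `data` plus an
#' `_id`/source envelope. Ordering by document id makes re-export
#' deterministic.
#'
#' @param store a document store.
#' @param path output file.
#' @param source_id,status optional selectors.
#' @return number of documents written.
#' @export
export_jsonl <- function(store, path, source_id = NULL, status = NULL) {
  docs <- select_docs(store, source_id, status)
  lines <- vapply(docs, function(w) tree_to_json(export_payload(w)),
                  character(1))
  writeLines(lines, path)
  length(docs)
}

#' Export documents in search-engine bulk format
#'
#' Newline-delimited action/document pairs: an `{"index":{...}}` action line
#' (with `_id` = `sourceId:primaryKey`) followed by the document line — two
#' lines per document.
#'
#' @param store a document store.
#' @param path output file.
#' @param index_name target index name written into each action line.
#' @param source_id,status optional selectors.
#' @return number of documents written.
#' @export
export_bulk <- function(store, path, index_name = "records",
                        source_id = NULL, status = NULL) {
  docs <- select_docs(store, source_id, status)
  lines <- character(0)
  for (w in docs) {
    action <- tree_object(index = tree_object(
      `_index` = index_name,
      `_id` = paste0(w$source_id, ":", w$primary_key)))
    doc <- if (!is.null(w$transformed_record)) w$transformed_record
           else w$original_record
    lines <- c(lines, tree_to_json(action), tree_to_json(doc))
  }
  writeLines(lines, path)
  length(docs)
}

#' Export documents as one JSON file each
#'
#' File names are the sanitized document ids (no path separators survive).
#'
#' @param store a document store.
#' @param dir output directory (created if needed).
#' @param source_id,status optional selectors.
#' @return number of files written.
#' @export
export_files <- function(store, dir, source_id = NULL, status = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- select_docs(store, source_id, status)
  for (w in docs) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", w$doc_id),
                                ".json"))
    writeLines(tree_to_json(export_payload(w)), fn)
  }
  length(docs)
}
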