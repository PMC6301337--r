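# export formats: JSON lines, bulk actions, per-document files

populated_store <- function(n = 12L) {
  store <- MemoryStore$new()
  for (i in seq_len(n)) {
    w <- document_wrapper("srcX", sprintf("k%02d", i),
                          tree_object(raw = as.character(i)))
    w$transformed_record <- tree_object(
      id = sprintf("k%02d", i),
      values = tree_array(as.character(i), as.character(i * 2)))
    w <- wrapper_set_status(w, "finished")
    store$put(w)
  }
  store
}

test_that("JSON-lines export writes one parseable line per document", {
  store <- populated_store(12L)
  p <- tempfile(fileext = ".jsonl")
  expect_identical(export_jsonl(store, p, status = "finished"), 12L)
  lines <- readLines(p)
  expect_length(lines, 12L)
  for (i in seq_along(lines)) {
    t <- json_to_tree(lines[[i]])
    expect_identical(t[["sourceId"]], "srcX")
    # lossless: the data member reproduces the stored transformed tree
    expect_true(tree_equal(t[["data"]],
                           store$get(t[["_id"]])$transformed_record))
  }
})

test_that("empty selections produce empty exports, not errors", {
  store <- populated_store(3L)
  p <- tempfile()
  expect_identical(export_jsonl(store, p, status = "no-such-status"), 0L)
  expect_identical(readLines(p), character(0))
  expect_identical(export_bulk(store, p, status = "no-such-status"), 0L)
  expect_length(readLines(p), 0L)
  expect_identical(export_files(store, tempfile(), status = "nope"), 0L)
})

test_that("re-export of an unchanged store is byte-identical", {
  store <- populated_store(7L)
  p1 <- tempfile()
  p2 <- tempfile()
  export_jsonl(store, p1, status = "finished")
  export_jsonl(store, p2, status = "finished")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("bulk export emits an action line plus a document line per doc", {
  store <- populated_store(12L)
  p <- tempfile()
  expect_identical(export_bulk(store, p, index_name = "biocorpus",
                               status = "finished"), 12L)
  lines <- readLines(p)
  expect_length(lines, 24L)
  ids <- character(0)
  for (i in seq(1L, 23L, by = 2L)) {
    action <- json_to_tree(lines[[i]])
    expect_identical(action[["index"]][["_index"]], "biocorpus")
    ids <- c(ids, action[["index"]][["_id"]])
    doc <- json_to_tree(lines[[i + 1L]])
    expect_true(is_tree_object(doc))
  }
  # _id = sourceId:primaryKey is collision-free
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("file export writes one sanitized filename per document", {
  store <- MemoryStore$new()
  w <- document_wrapper("a/b", "k/1:2", tree_object(x = "1"))
  w$transformed_record <- tree_object(y = "2")
  store$put(w)
  d <- tempfile()
  expect_identical(export_files(store, d), 1L)
  fs <- list.files(d)
  expect_length(fs, 1L)
  expect_false(any(grepl("[/\\\\:]", fs)))
  expect_true(tree_equal(json_to_tree(file.path(d, fs))[["data"]],
                         tree_object(y = "2")))
})
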