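# wrappers and the document-store contract (memory and file backends)

test_that("wrapper status always equals the last history entry", {
  w <- document_wrapper("src", "k1", tree_object(a = "1"))
  expect_identical(w$status, "new")
  expect_identical(w$history[[length(w$history)]]$status, w$status)
  w <- wrapper_set_status(w, "transformed")
  w <- wrapper_set_status(w, "finished")
  expect_identical(w$status, "finished")
  expect_identical(vapply(w$history, `[[`, character(1), "status"),
                   c("new", "transformed", "finished"))
})

test_that("equal records give equal checksums regardless of member order", {
  w1 <- document_wrapper("s", "k", json_to_tree('{"a":"1","b":"2"}'))
  w2 <- document_wrapper("s", "k", json_to_tree('{"b":"2","a":"1"}'))
  expect_identical(w1$checksum, w2$checksum)
})

test_that("both store backends satisfy get(put(w)) = w", {
  for (store in list(MemoryStore$new(), FileStore$new(tempfile("fs-")))) {
    w <- document_wrapper("srcA", "key1", tree_object(
      x = "1", nested = tree_object(y = tree_array("a", "b"))))
    w$transformed_record <- tree_object(out = "v")
    store$put(w)
    got <- store$get(w$doc_id)
    expect_identical(got$doc_id, w$doc_id)
    expect_identical(got$checksum, w$checksum)
    expect_true(tree_equal(got$original_record, w$original_record))
    expect_true(tree_equal(got$transformed_record, w$transformed_record))
    expect_identical(length(got$history), length(w$history))

    store$update_status(w$doc_id, "done")
    expect_identical(store$get(w$doc_id)$status, "done")

    expect_identical(store$find_by_source_key("srcA", "key1")$doc_id,
                     w$doc_id)
    expect_null(store$find_by_source_key("srcA", "nope"))
    expect_identical(store$count(), 1L)
    expect_identical(store$ids(), w$doc_id)
    expect_error(store$update_status("ghost", "x"),
                 class = "crucible_record_error")
  }
})

test_that("select filters by source and status in stable id order", {
  store <- MemoryStore$new()
  for (i in 1:5) {
    w <- document_wrapper("s1", paste0("k", i), tree_object(i = as.character(i)))
    if (i %% 2 == 0) w <- wrapper_set_status(w, "finished")
    store$put(w)
  }
  store$put(document_wrapper("s2", "z", tree_object(a = "1")))
  expect_length(store$select(source_id = "s1"), 5L)
  expect_length(store$select(status = "finished"), 2L)
  expect_length(store$select(source_id = "s2", status = "new"), 1L)
  ids <- vapply(store$select(), `[[`, character(1), "doc_id")
  expect_identical(ids, sort(ids))
})
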