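# ingestion DSL parsing, cursor planning, streaming and duplicate detection

test_that("the three-service script parses with a validated alias graph", {
  fx <- gen_three_service_source(3, 4, seed = 7)
  sc <- parse_ingest_script(fx$script)
  types <- vapply(sc$statements, `[[`, character(1), "type")
  expect_identical(types, c("download", "download", "download", "partition",
                            "partition", "join", "join", "ingest"))
  expect_identical(sc$aliases,
                   c("projDl", "subjDl", "detail", "projects", "subjects",
                     "ps", "full"))
})

test_that("scripts without INGEST or with forward references are rejected", {
  expect_error(parse_ingest_script(
    'DOWNLOAD "http://x" TO a FORMAT xml;'),
    "must end with an INGEST")
  expect_error(parse_ingest_script(paste(
    'PARTITION p = dl ON "rows.row";',
    'DOWNLOAD "http://x" TO dl FORMAT xml;',
    "INGEST p;", sep = "\n")),
    "used before definition")
  expect_error(parse_ingest_script(paste(
    'DOWNLOAD "http://x" TO a FORMAT xml;',
    "INGEST a;",
    'DOWNLOAD "http://y" TO b FORMAT xml;', sep = "\n")),
    "must be the last")
  expect_error(parse_ingest_script(paste(
    'DOWNLOAD "http://x" TO a FORMAT tsv;', "INGEST a;", sep = "\n")),
    "unknown format")
})

test_that("the planned three-way join equals the nested-loop expectation", {
  fx <- gen_three_service_source(3, 4, seed = 7)
  f <- MockFetcher$new(fx$routes)
  recs <- cursor_collect(plan_ingestion(fx$script, fetcher = f))
  expect_length(recs, 12L)
  expect_identical(canon_set(recs), canon_set(fx$expected))
})

test_that("the parameterized endpoint is fetched once per distinct subject", {
  fx <- gen_three_service_source(3, 4, seed = 7)
  f <- MockFetcher$new(fx$routes)
  invisible(cursor_collect(plan_ingestion(fx$script, fetcher = f)))
  detail_hits <- grep("/subject/", f$log, value = TRUE)
  expect_length(detail_hits, length(fx$subject_ids))
  expect_identical(anyDuplicated(detail_hits), 0L)
})

test_that("empty partitions drain immediately and joins of them are empty", {
  fx <- gen_three_service_source(0, 4, seed = 7)
  f <- MockFetcher$new(fx$routes)
  cur <- plan_ingestion(fx$script, fetcher = f)
  expect_false(cur$has_next())
  expect_false(cur$has_next()) # sticky
})

test_that("fixture generation is a pure function of its seed", {
  a <- gen_three_service_source(3, 4, seed = 7)
  b <- gen_three_service_source(3, 4, seed = 7)
  expect_identical(a$routes, b$routes)
  expect_identical(canon_set(a$expected), canon_set(b$expected))
  c <- gen_three_service_source(3, 4, seed = 8)
  expect_false(identical(a$routes, c$routes))
})

test_that("join cursors agree with a brute-force nested-loop join", {
  left <- lapply(1:20, function(i) {
    tree_object(pid = as.character(sample(1:6, 1)), li = as.character(i))
  })
  right <- lapply(1:15, function(i) {
    tree_object(pid = as.character(sample(1:6, 1)), ri = as.character(i))
  })
  jc <- join_cursor(list_cursor(left), "$.'pid'", "$.'pid'", "r",
                    right_cursor_fn = function() list_cursor(right))
  got <- cursor_collect(jc)
  want <- list()
  for (l in left) for (r in right) {
    if (identical(l$pid, r$pid)) {
      m <- l
      m[["r"]] <- r
      want[[length(want) + 1L]] <- m
    }
  }
  expect_identical(canon_set(got), canon_set(want))

  empty <- join_cursor(list_cursor(left), "$.'pid'", "$.'pid'", "r",
                       right_cursor_fn = function() list_cursor(list()))
  expect_length(cursor_collect(empty), 0L)
})

test_that("XML partitioning is streaming: first record after <1% of input", {
  f <- tempfile(fileext = ".xml")
  con <- file(f, "w")
  writeLines("<rows>", con, sep = "")
  for (i in seq_len(20000)) {
    writeLines(sprintf(
      "<row><id>%d</id><v>%s</v><pad>%s</pad></row>",
      i, paste0("val", i), strrep("x", 120)), con, sep = "")
  }
  writeLines("</rows>", con)
  close(con)

  cur <- partition_cursor(f, "xml", "rows.row")
  expect_true(cur$has_next())
  first <- cur$next_record()
  expect_identical(first[["id"]][["_$"]], "1")
  frac <- attr(cur, "bytes_read")() / file.size(f)
  expect_lt(frac, 0.01)
  n <- 1L
  while (cur$has_next()) {
    cur$next_record()
    n <- n + 1L
  }
  expect_identical(n, 20000L)
  unlink(f)
})

test_that("CSV partitioning yields one flat tree per data row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,name,score", "1,alpha,10", '2,"be,ta",20', "3,gamma,"), f)
  recs <- cursor_collect(partition_cursor(f, "csv"))
  expect_length(recs, 3L)
  expect_identical(recs[[2L]],
                   tree_object(id = "2", name = "be,ta", score = "20"))
  expect_identical(recs[[3L]][["score"]], "")
  unlink(f)
})

test_that("EXTRACT pulls a named member out of a tar bundle", {
  work <- tempfile("bundle-")
  dir.create(file.path(work, "data"), recursive = TRUE)
  writeLines("<rows><row><id>a</id></row><row><id>b</id></row></rows>",
             file.path(work, "data", "records.xml"))
  old <- setwd(work)
  tar("bundle.tar", files = "data")
  setwd(old)
  script <- paste(
    paste0('DOWNLOAD "file://', file.path(work, "bundle.tar"),
           '" TO bun FORMAT xml;'),
    'EXTRACT rec FROM bun NAME "*.xml";',
    'PARTITION rows = rec ON "rows.row";',
    "INGEST rows;", sep = "\n")
  recs <- cursor_collect(plan_ingestion(script))
  expect_length(recs, 2L)
  expect_identical(recs[[1L]][["id"]][["_$"]], "a")
  unlink(work, recursive = TRUE)
})

test_that("SET parameters substitute into download URL templates", {
  routes <- list()
  routes[["http://x.local/v2/data"]] <-
    "<rows><row><id>1</id></row></rows>"
  script <- paste('SET ver = "v2";',
                  'DOWNLOAD "http://x.local/${ver}/data" TO dl FORMAT xml;',
                  'PARTITION p = dl ON "rows.row";',
                  "INGEST p;", sep = "\n")
  recs <- cursor_collect(plan_ingestion(script,
                                        fetcher = MockFetcher$new(routes)))
  expect_length(recs, 1L)
  # caller-supplied params override SET
  routes[["http://x.local/v3/data"]] <- "<rows></rows>"
  recs3 <- cursor_collect(plan_ingestion(
    script, params = list(ver = "v3"), fetcher = MockFetcher$new(routes)))
  expect_length(recs3, 0L)
})

test_that("run_ingestion reports new/duplicate/updated against the store", {
  fx <- gen_three_service_source(3, 4, seed = 7)
  store <- MemoryStore$new()
  r1 <- run_ingestion(fx$descriptor, store, MockFetcher$new(fx$routes))
  expect_identical(r1[c("seen", "new", "updated", "duplicate", "errors")],
                   list(seen = 12L, new = 12L, updated = 0L, duplicate = 0L,
                        errors = 0L))
  r2 <- run_ingestion(fx$descriptor, store, MockFetcher$new(fx$routes))
  expect_identical(r2[c("seen", "new", "updated", "duplicate")],
                   list(seen = 12L, new = 0L, updated = 0L, duplicate = 12L))
  mut <- gen_three_service_source(3, 4, seed = 7,
                                  mutate_sid = fx$subject_ids[[5L]])
  r3 <- run_ingestion(mut$descriptor, store, MockFetcher$new(mut$routes))
  expect_identical(r3[c("new", "updated", "duplicate")],
                   list(new = 0L, updated = 1L, duplicate = 11L))
})

test_that("the web-service, csv and two-stage ingest methods produce records", {
  # web-service
  cs <- make_corpus_source(5, seed = 3)
  store <- MemoryStore$new()
  rep <- run_ingestion(cs$descriptor, store, MockFetcher$new(cs$routes))
  expect_identical(rep$new, 5L)

  # csv
  f <- tempfile(fileext = ".csv")
  writeLines(c("key,v", "k1,a", "k2,b"), f)
  desc <- source_descriptor("csvsrc", "csv source", "csv",
                            list(url = paste0("file://", f),
                                 primaryKeyPath = "$.'key'"))
  rep2 <- run_ingestion(desc, store)
  expect_identical(rep2$new, 2L)

  # two-stage: listing of ids, then one detail call per id
  routes <- list()
  routes[["http://ts.local/list"]] <-
    "<rows><row><id>A</id></row><row><id>B</id></row></rows>"
  routes[["http://ts.local/detail/${id}"]] <- function(url) {
    id <- sub(".*/", "", url)
    paste0("<item><id>", id, "</id><payload>p-", id, "</payload></item>")
  }
  desc3 <- source_descriptor(
    "ts", "two stage", "two-stage-web-service",
    list(listUrl = "http://ts.local/list", recordPath = "rows.row",
         idPath = "$.'id'.'_$'",
         detailUrlTemplate = "http://ts.local/detail/${id}",
         primaryKeyPath = "$.'id'.'_$'"))
  f3 <- MockFetcher$new(routes)
  rep3 <- run_ingestion(desc3, store, f3)
  expect_identical(rep3$new, 2L)
  expect_length(grep("/detail/", f3$log), 2L)
})

test_that("descriptor validation names the missing parameters", {
  expect_error(source_descriptor("s", "n", "web-service",
                                 list(url = "http://x")),
               "recordPath")
  expect_error(source_descriptor("s", "n", "teleport", list()),
               "unknown ingest method")
})
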