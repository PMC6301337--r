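# shared helpers for the suite: order-insensitive set comparison, a larger
# generated corpus source, and a standard three-stage pipeline configuration

canon_set <- function(trees) sort(vapply(trees, crucible:::tree_canonical,
                                         character(1)))

match_values <- function(ms) vapply(ms, function(m) {
  crucible:::tree_canonical(m$value)
}, character(1))

match_locations <- function(ms) lapply(ms, `[[`, "location")

expect_same_matches <- function(a, b) {
  expect_identical(match_values(a), match_values(b))
  expect_identical(match_locations(a), match_locations(b))
}

# a single-endpoint XML source with n records, served by a MockFetcher
make_corpus_source <- function(n, seed = 1L, payload_bytes = 0L) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i) {
    pad <- if (payload_bytes > 0L) {
      paste0("<pad>", paste(rep("x", payload_bytes), collapse = ""), "</pad>")
    } else ""
    sprintf("<row><id>R%06d</id><val>%s</val>%s</row>", i,
            paste0(sample(letters, 6), collapse = ""), pad)
  }, character(1))
  xml <- paste0("<rows>", paste(rows, collapse = ""), "</rows>")
  url <- "http://corpus.local/records"
  routes <- list()
  routes[[url]] <- xml
  descriptor <- source_descriptor(
    source_id = "corpus", name = "generated corpus",
    ingest_method = "web-service",
    params = list(url = url, recordPath = "rows.row",
                  primaryKeyPath = "$.'id'.'_$'"))
  list(routes = routes, descriptor = descriptor, n = n)
}

make_test_config <- function(export_dir = tempfile("exp-")) {
  list(
    database = list(backend = "memory"),
    mq = list(backend = "memory", lease = 5),
    workflow = list("transform", "enhance", "export"),
    consumers = list(
      transform = list(
        class = "jsontl-transform", status = "transformed",
        script = paste0('transform column "$.\'id\'.\'_$\'" to "recordId";\n',
                        'transform column "$.\'val\'.\'_$\'" to "payload";')),
      enhance = list(class = "toy-enhancer", status = "enhanced",
                     tag = "suite"),
      export = list(class = "file-export", status = "exported",
                    dir = export_dir)
    ))
}
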