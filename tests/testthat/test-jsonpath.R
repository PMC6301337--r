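# source-path parsing/matching and destination-path construction

PDB_PATH <- paste0("$..'PDBx:database_PDB_revCategory'",
                   ".'PDBx:database_PDB_rev'[?(@.'@num' = '1')]",
                   ".'PDBx:date'.'_$'")

pdb_rev_fixture <- function() {
  xml_to_tree(paste0(
    '<PDBx:datablock xmlns:PDBx="http://x">',
    "<PDBx:database_PDB_revCategory>",
    '<PDBx:database_PDB_rev num="1"><PDBx:date>1999-01-08</PDBx:date>',
    "</PDBx:database_PDB_rev>",
    '<PDBx:database_PDB_rev num="2"><PDBx:date>2011-07-13</PDBx:date>',
    "</PDBx:database_PDB_rev>",
    "</PDBx:database_PDB_revCategory></PDBx:datablock>"))
}

test_that("the deep-scan filter path parses to the documented four steps", {
  p <- parse_source_path(PDB_PATH)
  expect_length(p$steps, 4L)
  expect_identical(vapply(p$steps, `[[`, character(1), "kind"),
                   c("deep", "child", "child", "child"))
  f <- p$steps[[2L]]$ops[[1L]]
  expect_identical(f[c("kind", "rel", "op", "literal")],
                   list(kind = "filter", rel = "@num", op = "eq",
                        literal = "1"))
})

test_that("the root path is an empty step list and matches the whole tree", {
  p <- parse_source_path("$")
  expect_length(p$steps, 0L)
  for (seed in c(1, 5, 9)) {
    t <- gen_random_tree(3, 3, seed = seed)
    ms <- jp_match(t, p)
    expect_length(ms, 1L)
    expect_identical(ms[[1L]]$value, t)
    expect_length(ms[[1L]]$location, 0L)
  }
})

test_that("parse -> unparse -> parse is stable over random paths", {
  for (seed in 1:200) {
    t <- gen_random_tree(4, 4, seed = seed)
    p <- gen_random_path(t, seed = seed * 31L)
    u <- unparse_source_path(p)
    expect_identical(unparse_source_path(parse_source_path(u)), u)
  }
})

test_that("path syntax errors carry a position; filter operators are closed", {
  expect_error(parse_source_path("x.'a'"), class = "crucible_parse_error")
  expect_error(parse_source_path("$.'a"), "unterminated")
  expect_error(parse_source_path("$.'a'[?(@.'b' > '1')]"),
               "unknown filter operator")
})

test_that("the revision filter selects exactly the @num='1' entry", {
  ms <- jp_match(pdb_rev_fixture(), PDB_PATH)
  expect_length(ms, 1L)
  expect_identical(ms[[1L]]$value, "1999-01-08")
  expect_identical(jp_resolve_location(pdb_rev_fixture(), ms[[1L]]$location),
                   "1999-01-08")
})

test_that("matching equals the brute-force oracle on random tree/path pairs", {
  for (seed in 1:250) {
    t <- gen_random_tree(4, 4, seed = seed)
    p <- gen_random_path(t, seed = seed * 17L)
    expect_same_matches(jp_match(t, p), brute_force_match(t, p))
  }
})

test_that("matching is pure and locations resolve to their values", {
  for (seed in c(2, 11, 23)) {
    t <- gen_random_tree(4, 4, seed = seed)
    p <- gen_random_path(t, seed = seed + 100L)
    m1 <- jp_match(t, p)
    m2 <- jp_match(t, p)
    expect_identical(m1, m2)
    for (m in m1) {
      expect_identical(jp_resolve_location(t, m$location), m$value)
    }
  }
})

test_that("child distributes over arrays and wildcard iterates them", {
  t <- json_to_tree('{"a":[{"b":{"c":"1"}},{"b":{"c":"2"}}]}')
  expect_identical(match_values(jp_match(t, "$.'a'.'b'.'c'")),
                   match_values(jp_match(t, "$.'a'[*].'b'.'c'")))
  expect_length(jp_match(t, "$.'a'[1].'b'"), 1L)
  expect_length(jp_match(t, "$.'a'[5]"), 0L)
  expect_length(jp_match(t, "$.'nope'"), 0L)
})

test_that("destination paths parse to the documented step kinds", {
  p1 <- parse_dest_path("identifiers[].ID")
  expect_identical(lapply(p1$steps, `[[`, "kind"), list("append", "child"))
  p2 <- parse_dest_path("taxonomicInformation[0].name")
  expect_identical(p2$steps[[1L]][c("kind", "name", "i")],
                   list(kind = "at", name = "taxonomicInformation", i = 0L))
  expect_identical(parse_dest_path("a")$steps[[1L]]$kind, "child")
  expect_error(parse_dest_path("a[x]"), class = "crucible_parse_error")
})

test_that("set_value creates branches, appends, pads indices, overwrites", {
  d <- set_value(tree_object(), "dataRepository.name", "Protein Data Bank")
  expect_identical(d, tree_object(
    dataRepository = tree_object(name = "Protein Data Bank")))

  d2 <- set_value(set_value(tree_object(), "identifiers[].ID", "X"),
                  "identifiers[].ID", "Y")
  expect_identical(d2, tree_object(identifiers = tree_array(
    tree_object(ID = "X"), tree_object(ID = "Y"))))

  expect_identical(set_value(tree_object(a = 1), "a", 2), tree_object(a = 2))

  d3 <- set_value(tree_object(), "arr[2].v", "x")
  expect_length(d3[["arr"]], 3L)
  expect_identical(d3[["arr"]][[1L]], tree_object())

  expect_error(set_value(tree_object(a = "scalar"), "a.b", "v"),
               class = "crucible_transform_error")
})

test_that("set_value leaves unrelated branches untouched", {
  for (seed in c(3, 7, 19)) {
    t <- gen_random_tree(3, 3, seed = seed)
    if (!is_tree_object(t)) t <- tree_object(wrap = t)
    before <- tree_to_json(t)
    out <- set_value(t, "completely.new.branch", "v")
    expect_identical(tree_to_json(t), before) # input not mutated
    out[["completely"]] <- NULL
    expect_identical(tree_to_json(out), before)
  }
})
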