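# transform-engine semantics per statement type, dates, identity generation

test_that("constant + landing-page script build the documented destination", {
  src <- json_to_tree(paste0(
    '{"PDBx:datablock":{"@datablockName":"1ABC",',
    '"PDBx:atom_sites":{"@entry_id":"1ABC"}}}'))
  sc <- parse_script(paste0(
    'let "dataRepository.name" = "Protein Data Bank";\n',
    'transform column "$.\'PDBx:datablock\'.\'PDBx:atom_sites\'',
    '.\'@entry_id\'" to "access.landingPage" apply ',
    "{{ result ='http://www.rcsb.org/pdb/explore/explore.do?structureId=' ",
    "+ value}};"))
  out <- execute_script(sc, src)
  expect_identical(out, tree_object(
    dataRepository = tree_object(name = "Protein Data Bank"),
    access = tree_object(landingPage = paste0(
      "http://www.rcsb.org/pdb/explore/explore.do?structureId=1ABC"))))
})

test_that("an empty script yields an empty destination", {
  expect_identical(execute_script(parse_script(""), gen_random_tree(seed = 4)),
                   tree_object())
})

test_that("EVA name/value pairs reify into named members", {
  src <- json_to_tree(paste0(
    '{"metadata":[{"name":"species","value":"rat"},',
    '{"name":"region","value":"CA1"}]}'))
  sc <- parse_script(paste0(
    'transform column "$.\'metadata\'[*].\'value\'" to "metadata.value" ',
    'assign name from "$.\'metadata\'[*].\'name\'";'))
  expect_identical(execute_script(sc, src),
                   tree_object(metadata = tree_object(species = "rat",
                                                      region = "CA1")))

  # mismatched name/value cardinality is a transform error
  bad <- json_to_tree(
    '{"metadata":[{"name":"a","value":"x"},{"name":"b"}]}')
  expect_error(execute_script(sc, bad), class = "crucible_transform_error")
})

test_that("statements matching nothing leave the destination unchanged", {
  sc <- parse_script('transform column "$.\'absent\'" to "a.b";')
  expect_identical(execute_script(sc, tree_object(x = "1")), tree_object())
})

test_that("columns alignment pads short paths with empty strings", {
  src <- json_to_tree('{"a":[{"v":"1"},{"v":"2"}],"b":[{"v":"9"}]}')
  sc <- parse_script(paste0(
    'transform columns "$.\'a\'[*].\'v\'", "$.\'b\'[*].\'v\'" to "out[]" ',
    "apply {{ result = value1 + '/' + value2 }};"))
  expect_identical(execute_script(sc, src),
                   tree_object(out = tree_array("1/9", "2/")))

  # both paths empty: no-op, even with a mandatory apply
  expect_identical(execute_script(sc, tree_object()), tree_object())
})

test_that("union preserves duplicates and path-then-document order", {
  src <- json_to_tree('{"a":[{"id":"1"},{"id":"2"}],"b":[{"id":"1"}]}')
  sc <- parse_script(paste0(
    'transform union "$.\'a\'[*].\'id\'", "$.\'b\'[*].\'id\'" to "ids[]";'))
  expect_identical(execute_script(sc, src),
                   tree_object(ids = tree_array("1", "2", "1")))
})

test_that("join without apply emits one comma-separated scalar", {
  src <- json_to_tree('{"k":[{"v":"a"},{"v":"b"}]}')
  sc <- parse_script('join "$.\'k\'[*].\'v\'" to "joined";')
  expect_identical(execute_script(sc, src),
                   tree_object(joined = "a, b"))
})

test_that("every PDB-like fixture record transforms to its reference tree", {
  px <- gen_pdb_like_records(5L, seed = 2L)
  sc <- parse_script(attr(px, "script"))
  for (r in px) {
    expect_true(tree_equal(execute_script(sc, r$tree), r$expected))
  }
})

test_that("date normalization: pattern, free-form fallback, empty input", {
  expect_identical(to_standard_datetime("1999-01-08", "yyyy-MM-dd"),
                   "1999-01-08T00:00:00")
  expect_identical(to_standard_datetime("Jan 8, 1999"),
                   "1999-01-08T00:00:00")
  expect_identical(to_standard_datetime("8 January 1999"),
                   "1999-01-08T00:00:00")
  expect_identical(to_standard_datetime("1999-01-08 13:45:10",
                                        "yyyy-MM-dd HH:mm:ss"),
                   "1999-01-08T13:45:10")
  expect_error(to_standard_datetime(""), class = "crucible_transform_error")
  expect_error(to_standard_datetime("not a date"),
               class = "crucible_transform_error")
})

test_that("plugin functions register once and are callable from scripts", {
  reg <- function_registry()
  expect_error(register_function(reg, "toStandardDateTime", identity),
               "already registered")
  register_function(reg, "shout", function(value, args) toupper(value))
  sc <- parse_script('transform column "$.\'a\'" to "b" apply shout();')
  expect_identical(execute_script(sc, tree_object(a = "hi"), registry = reg),
                   tree_object(b = "HI"))
  # unregistered functions fail loudly
  expect_error(execute_script(sc, tree_object(a = "hi")),
               class = "crucible_transform_error")
})

test_that("identity scripts reproduce their sample records", {
  expect_identical(
    unparse_script(generate_identity_script(json_to_tree('{"a":{"b":"x"}}'))),
    'transform column "$.\'a\'.\'b\'" to "a.b";')
  expect_length(generate_identity_script(tree_object())$statements, 0L)
  for (seed in 1:15) {
    t <- gen_random_tree(4, 4, seed = seed)
    if (!is_tree_object(t)) t <- tree_object(root = t)
    expect_true(tree_equal(execute_script(generate_identity_script(t), t), t))
  }
})

test_that("execution is deterministic and incremental", {
  px <- gen_pdb_like_records(2L, seed = 9L)
  sc <- parse_script(attr(px, "script"))
  src <- px[[1L]]$tree
  full <- execute_script(sc, src)
  expect_identical(execute_script(sc, src), full)

  # running [1..k] then [k+1..n] on the running destination is equivalent
  for (k in c(2L, 5L)) {
    head_sc <- structure(list(statements = sc$statements[seq_len(k)]),
                         class = "tl_script")
    tail_sc <- structure(
      list(statements = sc$statements[seq(k + 1L, length(sc$statements))]),
      class = "tl_script")
    staged <- execute_script(tail_sc, src,
                             dest = execute_script(head_sc, src))
    expect_identical(staged, full)
  }
})

test_that("strict mode aborts with the statement index; lenient mode skips", {
  sc <- parse_script(paste0(
    'let "a" = "1";\n',
    'transform column "$.\'x\'" to "a.b";')) # a is a scalar: type conflict
  src <- tree_object(x = "v")
  err <- tryCatch(execute_script(sc, src), condition = function(e) e)
  expect_s3_class(err, "crucible_transform_error")
  expect_match(conditionMessage(err), "statement 2")
  expect_warning(out <- execute_script(sc, src, strict = FALSE),
                 "statement 2")
  expect_identical(out, tree_object(a = "1"))
})
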