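# document model: XML/CSV/JSON conversion, canonical checksums

test_that("XML elements map to objects with @-attributes and _$ text", {
  t <- xml_to_tree('<rev num="1"><date>1999-01-08</date></rev>')
  expect_identical(t, tree_object(`@num` = "1",
                                  date = tree_object(`_$` = "1999-01-08")))

  expect_identical(xml_to_tree("<a/>"), tree_object())
  expect_true(is_tree_object(xml_to_tree("<a/>")))

  t2 <- xml_to_tree("<r><x>1</x><x>2</x></r>")
  expect_identical(t2, tree_object(x = tree_array(
    tree_object(`_$` = "1"), tree_object(`_$` = "2"))))
})

test_that("repeated-sibling collapse agrees with an independent DOM walk", {
  xml <- paste0("<root a='1'><k><v>x</v></k><k><v>y</v></k>",
                "<solo>z</solo><k><v>w</v></k></root>")
  t <- xml_to_tree(xml)

  # oracle: plain xml2 DOM walk collecting same-named siblings into lists
  doc <- xml2::read_xml(xml)
  kids <- xml2::xml_children(doc)
  nm <- xml2::xml_name(kids)
  expect_identical(names(t), c("@a", unique(nm)))
  expect_length(t[["k"]], sum(nm == "k"))
  expect_identical(vapply(t[["k"]], function(o) o[["v"]][["_$"]],
                          character(1)),
                   xml2::xml_text(xml2::xml_find_all(doc, ".//k/v")))
  # document order of siblings is preserved
  expect_identical(t[["k"]][[2L]][["v"]][["_$"]], "y")
})

test_that("namespace prefixes are kept verbatim; CDATA is text; mixed text joins", {
  t <- xml_to_tree(paste0('<PDBx:r xmlns:PDBx="http://x">',
                          "<PDBx:d><![CDATA[a<b]]></PDBx:d>",
                          "<m>one<i>skip</i>two</m></PDBx:r>"))
  expect_identical(t[["PDBx:d"]][["_$"]], "a<b")
  expect_identical(t[["m"]][["_$"]], "one two")
  expect_identical(names(t[["m"]]), c("i", "_$"))
})

test_that("malformed XML raises a parse error", {
  expect_error(xml_to_tree("<a><b></a>"), class = "crucible_parse_error")
})

test_that("CSV rows zip against the header; arity violations are record errors", {
  expect_identical(csv_row_to_tree(c("a", "b"), c("1", "x")),
                   tree_object(a = "1", b = "x"))
  expect_identical(csv_row_to_tree(c("a"), NA_character_),
                   tree_object(a = ""))
  expect_error(csv_row_to_tree(c("a"), character(0)),
               class = "crucible_record_error")
})

test_that("JSON round trip is the identity on generated trees", {
  for (seed in 1:25) {
    t <- gen_random_tree(max_depth = 4, max_fanout = 4, seed = seed)
    expect_true(tree_equal(json_to_tree(tree_to_json(t)), t))
    # exact member order must also survive
    expect_identical(tree_to_json(json_to_tree(tree_to_json(t))),
                     tree_to_json(t))
  }
  expect_identical(tree_to_json(tree_object()), "{}")
  expect_identical(json_to_tree("{}"), tree_object())
})

test_that("checksums ignore member order, respect types, and are stable", {
  expect_identical(tree_checksum(tree_object(a = 1, b = 2)),
                   tree_checksum(tree_object(b = 2, a = 1)))
  expect_false(tree_checksum(tree_object(a = 1)) ==
                 tree_checksum(tree_object(a = "1")))

  sums <- character(0)
  canon <- character(0)
  for (seed in 1:100) {
    t <- gen_random_tree(4, 4, seed = seed)
    s1 <- tree_checksum(t)
    s2 <- tree_checksum(json_to_tree(tree_to_json(t))) # re-serialize, re-hash
    expect_identical(s1, s2)
    sums <- c(sums, s1)
    canon <- c(canon, crucible:::tree_canonical(t))
  }
  # distinct contents never collide; equal contents always agree
  expect_identical(length(unique(sums)), length(unique(canon)))
})
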