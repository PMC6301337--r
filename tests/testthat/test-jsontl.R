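# JSONTL lexing and parsing

test_that("a constant statement parses to destination + literal", {
  sc <- parse_script('let "dataRepository.name" = "Protein Data Bank";')
  expect_length(sc$statements, 1L)
  st <- sc$statements[[1L]]
  expect_identical(st$type, "constant")
  expect_identical(unparse_dest_path(st$dest), "dataRepository.name")
  expect_identical(st$literal, "Protein Data Bank")
})

test_that("assign name from is captured on single-path statements", {
  sc <- parse_script(paste0(
    'transform column "$.\'metadata\'[*].\'value\'" to "metadata.value" ',
    'assign name from "$.\'metadata\'[*].\'name\'";'))
  st <- sc$statements[[1L]]
  expect_identical(st$type, "single")
  expect_identical(unparse_source_path(st$assign_name_from),
                   "$.'metadata'[*].'name'")
})

test_that("a script of all five statement variants round-trips", {
  txt <- pdb_like_script()
  sc <- parse_script(txt)
  expect_identical(vapply(sc$statements, `[[`, character(1), "type"),
                   c("constant", "single", "single", "columns", "union",
                     "join", "single", "constant"))
  # parse . unparse . parse is structurally idempotent
  u1 <- unparse_script(sc)
  expect_identical(unparse_script(parse_script(u1)), u1)
  # the {{ }} bodies are captured verbatim
  expect_match(sc$statements[[4L]]$apply$code, "re\\.split", all = FALSE)
  expect_identical(sc$statements[[4L]]$apply$kind, "script")
  expect_identical(sc$statements[[3L]]$apply,
                   list(kind = "function", name = "toStandardDateTime",
                        args = "yyyy-MM-dd"))
})

test_that("keywords are case-insensitive, comments stripped, errors located", {
  sc <- parse_script(paste0("// leading comment\n",
                            'LET "a.b" = "c"; // trailing\n'))
  expect_identical(sc$statements[[1L]]$type, "constant")

  err <- tryCatch(parse_script('let "a" = = "b";'),
                  condition = function(e) e)
  expect_s3_class(err, "crucible_parse_error")
  expect_match(conditionMessage(err), "line 1")

  expect_error(parse_script('munge "a" to "b";'), "statement keyword")
  expect_error(parse_script('transform columns "$.\'a\'" to "b";'),
               "requires an apply")
})

test_that("join statements refuse conditions; other statements accept them", {
  expect_error(parse_script(paste0(
    'if "$.\'a\'" exists then join "$.\'b\'" to "c";')),
    "cannot carry a condition")
  sc <- parse_script(paste0(
    'if "$.\'SourceAccession\'" like "%GSE%" then ',
    'let "datasetDistributions[2].storedIn" = "Gene Expression Omnibus";'))
  st <- sc$statements[[1L]]
  expect_identical(st$condition$op, "like")
  expect_identical(st$condition$literal, "%GSE%")
})

test_that("conditions parse comparisons, existence, and boolean structure", {
  c1 <- parse_condition('"$.\'SourceAccession\'" like "%GSE%"')
  expect_identical(c1[c("type", "op", "literal")],
                   list(type = "cmp", op = "like", literal = "%GSE%"))

  c2 <- parse_condition('"$.\'a\'" exists')
  expect_identical(c2$op, "exists")
  expect_null(c2$literal)

  c3 <- parse_condition('"$.\'a\'" = "1" and "$.\'b\'" exists')
  expect_identical(c3$type, "and")
  expect_length(c3$args, 2L)

  # and binds tighter than or
  c4 <- parse_condition(
    '"$.\'a\'" = "1" or "$.\'b\'" = "2" and "$.\'c\'" not exists')
  expect_identical(c4$type, "or")
  expect_identical(c4$args[[2L]]$type, "and")

  expect_error(parse_condition('"$.\'a\'" ~ "x"'),
               class = "crucible_parse_error")
  expect_error(parse_condition('"$.\'a\'" ='), "end of input")
})

test_that("condition evaluation matches a direct boolean oracle", {
  cond <- parse_condition('"$.\'a\'" = "1" and "$.\'b\'" exists')
  cases <- list(
    list(tree = '{"a":"1","b":"x"}', a = TRUE, b = TRUE),
    list(tree = '{"a":"1"}', a = TRUE, b = FALSE),
    list(tree = '{"a":"2","b":"x"}', a = FALSE, b = TRUE),
    list(tree = '{"c":"9"}', a = FALSE, b = FALSE))
  for (cs in cases) {
    t <- json_to_tree(cs$tree)
    expect_identical(eval_condition(cond, t), cs$a && cs$b)
    expect_identical(
      eval_condition(parse_condition('"$.\'a\'" = "1" or "$.\'b\'" exists'),
                     t),
      cs$a || cs$b)
  }
  expect_true(eval_condition('"$.\'missing\'" not exists', tree_object()))
  expect_false(eval_condition('"$.\'missing\'" = "x"', tree_object()))
})
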