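# the sandboxed apply-block interpreter

test_that("string concatenation and identity blocks work", {
  expect_identical(run_apply_block("result = 'ncbitax:' + value",
                                   list(value = "9606")),
                   "ncbitax:9606")
  expect_identical(run_apply_block("result = value", list(value = "x")), "x")
})

test_that("regex splitting with extend matches an independent split", {
  code <- paste('arr=re.split("\\\\s*,\\\\s*",value1,)',
                'arr.extend(re.split("\\\\s*,\\\\s*",value2))',
                "result=arr", sep = "\n")
  v1 <- "a, b"
  v2 <- "c"
  got <- run_apply_block(code, list(value1 = v1, value2 = v2))
  want <- c(strsplit(v1, "\\s*,\\s*", perl = TRUE)[[1]],
            strsplit(v2, "\\s*,\\s*", perl = TRUE)[[1]])
  expect_identical(unlist(got), want)
})

test_that("try/except with 0-based index lookup selects by companion list", {
  code <- paste("i = -1",
                "try:",
                "    i = value1.index('scientific')",
                "except:",
                "    pass",
                "result = value2[i] if i >= 0 else ''", sep = "\n")
  expect_identical(
    run_apply_block(code, list(value1 = list("common", "scientific"),
                               value2 = list("human", "Homo sapiens"))),
    "Homo sapiens")
  expect_identical(
    run_apply_block(code, list(value1 = list("common"),
                               value2 = list("human"))),
    "")
})

test_that("flat (unindented) try/except bodies are accepted too", {
  code <- paste("i = -1", "try:", "i = value1.index('zz')", "except:",
                "pass", "result = i", sep = "\n")
  expect_identical(run_apply_block(code, list(value1 = list("a"))), -1)
})

test_that("the sandbox is closed: only bindings and builtins resolve", {
  expect_error(run_apply_block("result = file('x')", list()),
               class = "crucible_transform_error")
  expect_error(run_apply_block("result = unknown_name", list()),
               "not defined")
  expect_error(run_apply_block("x = 1", list()), "did not define 'result'")
})

test_that("string methods, numbers and conditionals behave as documented", {
  expect_identical(run_apply_block("result = value.strip().upper()",
                                   list(value = "  ab ")), "AB")
  expect_identical(run_apply_block("result = value.replace('-', '_')",
                                   list(value = "a-b")), "a_b")
  expect_identical(run_apply_block("result = len(value)",
                                   list(value = list("a", "b"))), 2L)
  expect_identical(run_apply_block("result = str(1 + 2)", list()), "3")
  expect_identical(
    run_apply_block("result = 'big' if len(value) > 2 else 'small'",
                    list(value = "abcd")),
    "big")
  expect_identical(run_apply_block("result = value[-1]",
                                   list(value = list("a", "b"))), "b")
})
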