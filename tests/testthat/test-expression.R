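test_that("functional and infix syntax parse to the same tree", {
  expect_identical(
    parse_expression("AND(InA, InB)"),
    parse_expression("InA AND InB")
  )
  expect_identical(
    parse_expression("OR(a, b)"),
    parse_expression("a OR b")
  )
  expect_identical(
    parse_expression("NOT(a)"),
    parse_expression("NOT a")
  )
  expect_identical(
    parse_expression("YES(a)"),
    parse_expression("a")
  )
  expect_identical(
    expr_to_string("a AND b OR c"), # AND binds tighter
    "OR(AND(a, b), c)"
  )
})

test_that("parse errors report the offending position", {
  err <- expect_error(parse_expression("AND(a,"), class = "dt_parse_error")
  expect_match(conditionMessage(err), "end of expression|expected")
  expect_error(parse_expression("a ** b"), class = "dt_parse_error")
  expect_error(parse_expression(""), class = "dt_parse_error")
  expect_error(parse_expression("NOT(a, b)"), class = "dt_parse_error")
})

test_that("expression evaluation follows Boolean semantics", {
  expect_true(eval_expression("AND(a, NOT(b))", c(a = TRUE, b = FALSE)))
  expect_false(eval_expression("AND(a, NOT(b))", c(a = TRUE, b = TRUE)))
  expect_true(eval_expression("OR(a, b, c)", c(a = FALSE, b = FALSE, c = TRUE)))
  expect_identical(expr_inputs("AND(x, OR(y, NOT(z)))"), c("x", "y", "z"))
})

test_that("fan-in above four per bridge is rejected", {
  expect_error(
    dnatransformr:::normalize_expression("AND(a, b, c, d, e)"),
    class = "dt_unsupported_fanin"
  )
  expect_error(
    dnatransformr:::normalize_expression("OR(a, b, c, d, e)"),
    class = "dt_unsupported_fanin"
  )
})

test_that("mixed positive/negative clauses are flagged as unrealizable", {
  expect_error(
    dnatransformr:::normalize_expression("a OR NOT(b)"),
    class = "dt_unrealizable_expression"
  )
  expect_error(
    dnatransformr:::normalize_expression("AND(a, NOT(a))"),
    class = "dt_unrealizable_expression"
  )
})

test_that("normalization maps gate families to the expected architecture plan", {
  plan <- dnatransformr:::normalize_expression("AND(a, b)")
  expect_length(plan$shields, 1)
  expect_identical(plan$shields[[1]]$terms, list(c("a", "b")))
  expect_true(plan$constitutive_marker)

  plan <- dnatransformr:::normalize_expression("NOT(a)")
  expect_length(plan$shields, 0)
  expect_length(plan$markers, 1)

  # AND of NOTs merges into a single multi-junction marker bridge
  plan <- dnatransformr:::normalize_expression("AND(NOT(a), NOT(b))")
  expect_length(plan$markers, 1)
  expect_identical(plan$markers[[1]]$terms, list("a", "b"))

  # composite: one shield bridge plus one marker bridge
  plan <- dnatransformr:::normalize_expression("AND(OR(a, b), NOT(c))")
  expect_length(plan$shields, 1)
  expect_length(plan$markers, 1)
})
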