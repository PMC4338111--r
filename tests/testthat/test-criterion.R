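test_that("the differential-expression criterion parses to the expected tree", {
  cr <- parse_criterion("ABS([log2FC]) > 1 AND [pvalue] < 0.05")
  ast <- cr$ast
  expect_equal(ast$op, "and")
  expect_equal(ast$lhs$op, "cmp"); expect_equal(ast$lhs$cmp, ">")
  expect_equal(ast$lhs$lhs$op, "abs")
  expect_equal(ast$lhs$lhs$arg$name, "log2FC")
  expect_equal(ast$lhs$rhs$value, 1)
  expect_equal(ast$rhs$cmp, "<")
  expect_equal(ast$rhs$lhs$name, "pvalue")
  expect_equal(ast$rhs$rhs$value, 0.05)
})

test_that("AND binds tighter than OR and NOT tighter than AND; parentheses override", {
  ast <- parse_criterion("[a] > 1 OR [b] > 1 AND [c] > 1")$ast
  expect_equal(ast$op, "or")
  expect_equal(ast$rhs$op, "and")

  ast2 <- parse_criterion("([a] > 1 OR [b] > 1) AND [c] > 1")$ast
  expect_equal(ast2$op, "and")
  expect_equal(ast2$lhs$op, "or")

  ast3 <- parse_criterion("NOT [a] > 1 AND [b] > 1")$ast
  expect_equal(ast3$op, "and")
  expect_equal(ast3$lhs$op, "not")

  # left associativity
  ast4 <- parse_criterion("[a] > 1 AND [b] > 1 AND [c] > 1")$ast
  expect_equal(ast4$lhs$op, "and")
  expect_equal(ast4$rhs$op, "cmp")
})

test_that("syntax errors carry the character position; unknown functions are named", {
  expect_error(parse_criterion("[a] >"), "position 6.*end of input")
  expect_error(parse_criterion("[a] > 1 AND"), "position 12")
  expect_error(parse_criterion("[a] ? 1"), "position 5")
  expect_error(parse_criterion("SQRT([a]) > 1"), "unknown function 'SQRT'")
  expect_error(parse_criterion("[] > 1"), "empty column reference")
})

test_that("evaluation is three-valued: missing propagates as undefined", {
  cr <- parse_criterion(demo_criterion)
  expect_true(evaluate_criterion(cr, list(log2FC = 1.5, pvalue = 0.01)))
  expect_false(evaluate_criterion(cr, list(log2FC = 0.5, pvalue = 0.01)))
  expect_identical(evaluate_criterion(cr, list(log2FC = NA_real_, pvalue = 0.01)), NA)
  # Kleene short-circuits: a definite FALSE absorbs an undefined AND branch
  expect_false(evaluate_criterion(cr, list(log2FC = NA_real_, pvalue = 0.5)))
  or_cr <- parse_criterion("[pvalue] < 0.05 OR [log2FC] > 1")
  expect_true(evaluate_criterion(or_cr, list(log2FC = NA_real_, pvalue = 0.01)))
})

test_that("string comparisons allow only equality operators and matching types", {
  row <- list(type = "up", fc = 2)
  expect_true(evaluate_criterion('[type] = "up"', row))
  expect_false(evaluate_criterion("[type] <> 'up'", row))
  expect_error(evaluate_criterion('[type] < "up"', row), "not defined for strings.*type")
  expect_error(evaluate_criterion('[type] = 1', row), "type mismatch.*type")
  expect_error(evaluate_criterion("ABS([type]) > 1", row), "non-numeric.*type")
  expect_error(evaluate_criterion("[missing_col] > 1", row), "unknown column 'missing_col'")
})

test_that("Kleene laws hold: double negation, absorption of undefined", {
  rows <- list(list(a = 1, b = NA_real_), list(a = NA_real_, b = NA_real_),
               list(a = -1, b = 0))
  for (row in rows) {
    e <- "[a] > 0"
    expect_identical(evaluate_criterion(sprintf("NOT NOT %s", e), row),
                     evaluate_criterion(e, row))
    expect_false(evaluate_criterion("1 < 0 AND [b] > 0", row))  # FALSE AND U
    expect_true(evaluate_criterion("0 < 1 OR [b] > 0", row))    # TRUE OR U
  }
})

test_that("evaluation matches the exhaustive Kleene oracle on all shallow expressions", {
  atoms <- c("[x] > 0", "[y] > 0", "NOT [x] > 0")
  exprs <- enumerate_expressions(atoms, depth = 3L)
  vals <- c(-1, 1, NA_real_)
  grid <- expand.grid(x = vals, y = vals)
  for (txt in exprs) {
    cr <- parse_criterion(txt)
    for (i in seq_len(nrow(grid))) {
      row <- list(x = grid$x[i], y = grid$y[i])
      expect_identical(tri_of(evaluate_criterion(cr, row)),
                       oracle_eval(cr$ast, row),
                       label = sprintf("'%s' on x=%s y=%s", txt, grid$x[i], grid$y[i]))
    }
  }
})

test_that("random expressions over three comparisons match the truth-table oracle", {
  set.seed(77)
  tri_vals <- c(-1, 1, NA_real_)
  grid <- expand.grid(a = tri_vals, b = tri_vals, c = tri_vals)
  for (rep in 1:40) {
    atoms <- sprintf("[%s] %s %s", c("a", "b", "c"),
                     sample(c("<", ">", "<=", ">="), 3, replace = TRUE),
                     sample(c(-1, 0, 1), 3, replace = TRUE))
    shuffled <- sample(atoms)
    txt <- sprintf("(%s %s %s) %s NOT %s", shuffled[1],
                   sample(c("AND", "OR"), 1), shuffled[2],
                   sample(c("AND", "OR"), 1), shuffled[3])
    cr <- parse_criterion(txt)
    for (i in seq_len(nrow(grid))) {
      row <- as.list(grid[i, ])
      expect_identical(tri_of(evaluate_criterion(cr, row)),
                       oracle_eval(cr$ast, row))
    }
  }
})

test_that("pretty-printed criteria reparse to the identical tree", {
  set.seed(123)
  for (rep in 1:200) {
    txt <- random_expr_text(3L)
    cr <- parse_criterion(txt)
    printed <- format(cr)
    expect_identical(parse_criterion(printed)$ast, cr$ast,
                     label = sprintf("'%s' -> '%s'", txt, printed))
  }
})
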