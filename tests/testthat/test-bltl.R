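test_that("the parser builds the expected trees", {
  f <- parse_formula("F[10](x > 1e11)")
  expect_identical(f$kind, "until")
  expect_identical(f$bound, 10)
  expect_identical(f$right$kind, "atom")
  expect_identical(f$right$var, "x")
  expect_identical(f$right$rel, ">")
  expect_identical(f$right$value, 1e11)
  # F desugars to (phi | !phi) U phi
  expect_identical(f$left$kind, "or")
  expect_identical(f$left$right$kind, "not")

  f2 <- parse_formula("F[10](x > 3.3)")
  expect_identical(f2$right$value, 3.3)

  g <- parse_formula("x > 3 & !(y < 2)")
  expect_identical(g$kind, "and")
  expect_identical(g$left$kind, "atom")
  expect_identical(g$right$kind, "not")
  expect_identical(g$right$child$var, "y")

  u <- parse_formula("(x>0) U[2.5] (y=1)")
  expect_identical(u$kind, "until")
  expect_identical(u$bound, 2.5)
  expect_setequal(formula_variables(u), c("x", "y"))

  # precedence: ! binds tighter than &, & tighter than |
  h <- parse_formula("a > 0 | b > 0 & !c > 0")
  expect_identical(h$kind, "or")
  expect_identical(h$right$kind, "and")
})

test_that("syntax errors report a position and bad operators are rejected", {
  expect_error(parse_formula("x >"), "expected a number")
  expect_error(parse_formula("x >= 3"), "position")
  expect_error(parse_formula("F[10] x > 1"), "expected '\\('")
  expect_error(parse_formula("(x > 1"), "expected '\\)'")
  expect_error(parse_formula("x > 1 # y"), "unexpected character")
  expect_error(parse_formula("x > 1 y > 2"), "trailing")
  expect_error(parse_formula("F[-1](x > 0)"), ">= 0")
})

test_that("satisfaction follows the five semantic rules", {
  # rule 1 (atoms) on a single state
  one <- bltl_trace(5, 0, "x")
  expect_true(bltl_satisfies(one, "x > 3"))
  expect_false(bltl_satisfies(one, "x < 3"))
  expect_true(bltl_satisfies(bltl_trace(1, 0, "x"), "x = 1"))

  # rules 2-4 (boolean connectives)
  tr <- bltl_trace(cbind(c(4, 0), c(1, 1)), c(1, 0), c("x", "y"))
  expect_true(bltl_satisfies(tr, "x > 3 & y = 1"))
  expect_false(bltl_satisfies(tr, "x > 3 & y < 1"))
  expect_true(bltl_satisfies(tr, "x > 3 | y < 1"))
  expect_false(bltl_satisfies(tr, "!(x > 3)"))
  expect_true(bltl_satisfies(tr, "!(x > 3)", at = 2))

  # rule 5: bound 0 demands the witness at the start index
  tr0 <- bltl_trace(c(5, 20), c(1, 0), "x")
  expect_false(bltl_satisfies(tr0, "(x>0) U[0] (x>10)"))
  expect_true(bltl_satisfies(tr0, "(x>0) U[0] (x>10)", at = 2))

  # rule 5: elapsed duration counts states before the witness only
  expect_true(bltl_satisfies(
    bltl_trace(c(0, 0, 0, 20), c(4, 4, 1, 0), "x"), "F[10](x > 10)"
  ))
  expect_false(bltl_satisfies(
    bltl_trace(c(0, 0, 0, 20), c(4, 4, 4, 0), "x"), "F[10](x > 10)"
  ))

  # left operand must hold strictly before the witness
  tru <- bltl_trace(c(1, -1, 20), c(1, 1, 0), "x")
  expect_false(bltl_satisfies(tru, "(x>0) U[5] (x>10)"))
  expect_true(bltl_satisfies(tru, "(x>-2) U[5] (x>10)"))

  # out-of-range start and unknown variables are errors
  expect_error(bltl_satisfies(one, "x > 0", at = 2), "outside the trace")
  expect_error(bltl_satisfies(one, "q > 0"), "variable 'q'")
})

test_that("temporal operators satisfy duality and bound monotonicity", {
  withr::local_seed(401)
  for (i in 1:200) {
    tr <- random_trace(8, c("x", "y"))
    phi <- random_formula(2, c("x", "y"))
    t1 <- round(runif(1, 0, 3), 2)
    t2 <- t1 + round(runif(1, 0, 2), 2)
    ftxt <- format(phi)
    g_direct <- bltl_satisfies(tr, sprintf("G[%g](%s)", t1, ftxt))
    g_dual <- bltl_satisfies(tr, sprintf("!(F[%g](!(%s)))", t1, ftxt))
    expect_identical(g_direct, g_dual)
    # F monotone in the bound
    f1 <- bltl_satisfies(tr, sprintf("F[%g](%s)", t1, ftxt))
    f2 <- bltl_satisfies(tr, sprintf("F[%g](%s)", t2, ftxt))
    if (f1) expect_true(f2)
    # De Morgan
    psi <- random_formula(2, c("x", "y"))
    lhs <- bltl_satisfies(tr, sprintf("!((%s) | (%s))", ftxt, format(psi)))
    rhs <- bltl_satisfies(tr, sprintf("!(%s) & !(%s)", ftxt, format(psi)))
    expect_identical(lhs, rhs)
    # double negation
    expect_identical(
      bltl_satisfies(tr, sprintf("!(!(%s))", ftxt)),
      bltl_satisfies(tr, ftxt)
    )
  }
})

test_that("an atom's verdict depends only on the state it is read at", {
  withr::local_seed(402)
  for (i in 1:50) {
    tr <- random_trace(8, "x")
    n <- nrow(tr$states)
    k <- sample(n, 1)
    v <- tr$states[k, 1]
    # rebuild the trace with all other states scrambled
    other <- matrix(round(runif(n, -2, 2), 1), n, 1)
    other[k, 1] <- v
    tr2 <- bltl_trace(other, tr$durations, "x")
    f <- sprintf("x > %g", round(runif(1, -2, 2), 1))
    expect_identical(bltl_satisfies(tr, f, at = k), bltl_satisfies(tr2, f, at = k))
  }
})

test_that("the optimised monitor agrees with the reference evaluator", {
  withr::local_seed(403)
  for (i in 1:500) {
    tr <- random_trace(8, c("x", "y"))
    f <- random_formula(4, c("x", "y"))
    k <- sample(nrow(tr$states), 1)
    expect_identical(
      bltl_satisfies(tr, f, at = k),
      bltl_satisfies_naive(tr, f, at = k),
      info = sprintf("case %d: %s at %d", i, format(f), k)
    )
  }
})
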