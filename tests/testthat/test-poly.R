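# Exact polynomial/rational-function kernel.

rnd_poly <- function(vars, nterms, maxdeg = 3) {
  expo <- matrix(sample(0:maxdeg, nterms * length(vars), replace = TRUE),
                 nterms, length(vars))
  linident:::lp_norm(vars, expo,
                     sample(c(-5:-1, 1:5), nterms, replace = TRUE),
                     sample(1:3, nterms, replace = TRUE))
}

test_that("parser, printer and arithmetic agree on algebraic identities", {
  p <- linident:::parse_expression("(p1+p2)*(p3+p4) - p2*p3")
  q <- linident:::parse_expression("p1*p3 + p1*p4 + p2*p4")
  expect_true(linident:::rf_equal(p, q))
  # printing round-trips through the parser
  s <- linident:::rf_to_string(p)
  expect_true(linident:::rf_equal(linident:::parse_expression(s), p))
  # decimal literals become exact rationals
  r <- linident:::parse_expression("0.7 + 0.7")
  expect_identical(r$num$num, 7)
  expect_identical(r$num$den, 5)
  # unparseable input is rejected
  expect_error(linident:::parse_expression("p1 +* 2"), "cannot parse")
})

test_that("ring axioms hold on random polynomials (fixed seed)", {
  set.seed(42)
  lp <- asNamespace("linident")
  for (i in 1:20) {
    a <- rnd_poly(c("x", "y", "z"), 4)
    b <- rnd_poly(c("y", "z", "w"), 3)
    c_ <- rnd_poly(c("x", "w"), 3)
    expect_true(lp$lp_equal(lp$lp_add(a, b), lp$lp_add(b, a)))
    expect_true(lp$lp_equal(lp$lp_mul(a, b), lp$lp_mul(b, a)))
    expect_true(lp$lp_equal(lp$lp_mul(a, lp$lp_add(b, c_)),
                            lp$lp_add(lp$lp_mul(a, b), lp$lp_mul(a, c_))))
    expect_true(lp$lp_is_zero(lp$lp_sub(a, a)))
    # derivative product rule
    v <- "y"
    lhs <- lp$lp_deriv(lp$lp_mul(a, b), v)
    rhs <- lp$lp_add(lp$lp_mul(lp$lp_deriv(a, v), b),
                     lp$lp_mul(a, lp$lp_deriv(b, v)))
    expect_true(lp$lp_equal(lhs, rhs))
  }
})

test_that("division and gcd invert multiplication", {
  set.seed(7)
  lp <- asNamespace("linident")
  for (i in 1:12) {
    a <- rnd_poly(c("x", "y"), 3, 2)
    b <- rnd_poly(c("y", "z"), 3, 2)
    if (lp$lp_is_zero(a) || lp$lp_is_zero(b)) next
    ab <- lp$lp_mul(a, b)
    expect_true(lp$lp_equal(lp$lp_divexact(ab, b), a))
    # gcd(a*b, b) is divisible by b (up to a rational scalar)
    g <- lp$lp_gcd(ab, b)
    q <- lp$lp_divmod(lp$lp_primitive(b), g)
    expect_true(lp$lp_is_zero(q$r))
    # gcd divides both inputs exactly
    expect_true(lp$lp_is_zero(lp$lp_divmod(ab, g)$r))
    expect_true(lp$lp_is_zero(lp$lp_divmod(b, g)$r))
  }
})

test_that("rational functions simplify to lowest terms", {
  r <- linident:::rf_div(linident:::parse_expression("p3*x10"),
                         linident:::parse_expression("p2*x10"))
  expect_identical(linident:::rf_to_string(r), "p3/p2")
  # evaluation agrees with plain arithmetic
  p <- linident:::parse_expression("(p1+p2)^2/(p1 - p2)")
  env <- c(p1 = 1.3, p2 = 0.4)
  expect_equal(linident:::rf_eval(p, env), (1.3 + 0.4)^2 / (1.3 - 0.4))
})

test_that("exact arithmetic refuses to round rather than losing precision", {
  expect_error(linident:::lp_const(2^60), "overflow")
})
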