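# Laplace-domain machinery: characteristic polynomial, state transforms,
# derivative matrices, sensitivity columns.

test_that("characteristic polynomial is det(sI - A)", {
  d1 <- characteristic_polynomial(ex1()$model)
  expect_true(linident:::rf_equal(
    d1, linident:::parse_expression("(s+p1+p2)*(s+p3+p4) - p2*p3")))
  tiny <- linear_model(A = matrix("-p", 1, 1), C = matrix("1", 1, 1))
  expect_true(linident:::rf_equal(characteristic_polynomial(tiny),
                                  linident:::parse_expression("s + p")))
  # the trap-state model factorizes through (s + p13)
  d2 <- characteristic_polynomial(ex2()$model)
  q <- linident:::lp_divmod(d2$num, poly_of("s + p13"))
  expect_true(linident:::lp_is_zero(q$r))
})

test_that("Laplace state solution matches the closed form of the two-compartment model", {
  m <- ex1()$model
  ls <- laplace_state(m, experiment(x0 = c("x10", "x20"), u0 = "U"),
                      input_mode = "generic")
  delta <- characteristic_polynomial(m)
  x1_expected <- linident:::parse_expression("(s+p3+p4)*(U+x10) + p3*x20")
  expect_true(linident:::rf_equal(ls$X_num[[1]], x1_expected))
  expect_true(linident:::rf_equal(ls$den, delta))
  # no excitation: X identically zero
  ls0 <- laplace_state(m, experiment(x0 = c(0, 0)))
  expect_true(all(vapply(ls0$X_num, linident:::rf_is_zero, logical(1))))
})

test_that("Laplace state agrees with the numeric matrix inverse (three compartments)", {
  m <- ex3()$model
  ls <- laplace_state(m, experiment(x0 = c(1.5, 0.5, 2), u0 = 3),
                      input_mode = "generic")
  vals <- c(p21 = 1, p31 = 2, p12 = 3, p13 = 0.4, p02 = 2, p03 = 3)
  for (s0 in c(0.7, 1.9)) {
    env <- c(vals, s = s0)
    An <- linident:::sm_eval(m$A, vals)
    ref <- solve(s0 * diag(3) - An, c(3 + 1.5, 0.5, 2))
    got <- vapply(ls$X_num, linident:::rf_eval, numeric(1), env = env) /
      linident:::rf_eval(ls$den, env)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("derivative matrices reproduce the printed block structure", {
  dm1 <- derivative_matrices(ex1()$model)
  expect_identical(dm1$M_A, matrix(c("-X1", "0", "-X1", "X1", "X2", "-X2", "0", "-X2"),
                                   2, 4, dimnames = list(NULL, c("p1", "p2", "p3", "p4"))))
  expect_identical(unname(dm1$M_C[1, 1]), "-X1/V^2")
  expect_equal(ncol(dm1$M_B), 0)   # no parameters in B
  dm4 <- derivative_matrices(ex4()$model)
  expect_equal(dim(dm4$M_A), c(4, 7))
  # column for p43 moves mass from pool 3 to pool 4
  expect_identical(unname(dm4$M_A[, "p43"]), c("0", "0", "-X3", "X3"))
})

test_that("sensitivity columns match the printed vectors up to common scaling", {
  sc <- sensitivity_columns(
    ex1()$model, ex1()$conditions$case1, parameters = RATES1)
  # with x20 = 0, u = 0 the printed sensitivity vector specializes to
  # (s+p3+p4)^2, (s+p4)(s+p3+p4), -p2(s+p4), p2*p3 times a common factor
  refs <- c("(s+p3+p4)^2", "(s+p4)*(s+p3+p4)", "-p2*(s+p4)", "p2*p3")
  # identical common scaling: ratios of entries agree symbolically
  q1 <- sc$columns[[1]][[1]]
  r1 <- poly_of(refs[1])
  for (j in 2:4) {
    lhs <- linident:::lp_mul(sc$columns[[j]][[1]], r1)
    rhs <- linident:::lp_mul(q1, poly_of(refs[j]))
    expect_true(linident:::lp_is_zero(linident:::lp_sub(lhs, rhs)),
                label = sprintf("column %d proportional", j))
  }
  expect_match(sc$cancelled, "x10")
})

test_that("trap-state model: q3 collapses to the printed product after clearing", {
  sc <- sensitivity_columns(ex2()$model, ex2()$conditions$x30_nonzero,
                            input_mode = "generic")
  q3 <- sc$columns[[which(sc$param_order == "p13")]][[1]]
  ref <- linident:::lp_mul(poly_of("p21*x30*s"), poly_of("s + p12 + p21"))
  # proportional up to a rational constant
  expect_equal(linident:::lp_total_degree(q3), linident:::lp_total_degree(ref))
  lead_ratio <- q3$num[1] / ref$num[1]
  expect_true(linident:::lp_is_zero(linident:::lp_sub(
    linident:::lp_scale(ref, lead_ratio, 1), q3)))
})

test_that("the shared nonzero factor (U + x10) cancels in the two-path model", {
  sc <- sensitivity_columns(ex3()$model, ex3()$conditions$structural,
                            input_mode = "generic")
  expect_match(sc$cancelled, "uc")
  expect_match(sc$cancelled, "x10")
  # after cancellation no condition symbol survives
  expect_length(coefficient_system(sc)$symbols_present, 0)
})

test_that("zero excitation raises the dedicated condition", {
  expect_error(sensitivity_columns(ex1()$model, experiment(x0 = c(0, 0))),
               class = "ident_no_excitation")
})

test_that("step and generic input conventions give identical verdicts on the benchmark cases", {
  cases <- list(
    list(ex1()$model, ex1()$conditions$case1, RATES1),
    list(ex1()$model, ex1()$conditions$case3a, RATES1),
    list(ex2()$model, ex2()$conditions$x30_zero, NULL),
    list(ex2()$model, ex2()$conditions$x30_nonzero, NULL),
    list(ex3()$model, ex3()$conditions$structural, NULL),
    list(ex4()$model, ex4()$conditions$fit, NULL))
  for (cs in cases) {
    pars <- if (is.null(cs[[3]])) cs[[1]]$parameters else cs[[3]]
    a <- identifiability(cs[[1]], cs[[2]], parameters = pars,
                         input_mode = "generic", combinations = FALSE)
    b <- identifiability(cs[[1]], cs[[2]], parameters = pars,
                         input_mode = "step", combinations = FALSE)
    expect_identical(a$status, b$status)
    expect_identical(a$n_max, b$n_max)
  }
})
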