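# Model construction, validation, fixtures, random generator, serialization.

test_that("parameters are inferred from the matrices and dimensions validated", {
  m1 <- ex1()$model
  expect_equal(m1$n_x, 2); expect_equal(m1$n_y, 1); expect_equal(m1$n_u, 1)
  expect_setequal(m1$parameters, c("p1", "p2", "p3", "p4", "V"))

  tiny <- linear_model(A = matrix("-p", 1, 1), C = matrix("1", 1, 1))
  expect_equal(tiny$n_x, 1)
  expect_equal(tiny$parameters, "p")

  m4 <- ex4()$model
  expect_equal(m4$n_x, 4); expect_equal(m4$n_y, 2)
  expect_length(m4$parameters, 7)

  expect_error(linear_model(A = matrix("p", 2, 1), C = matrix("1", 1, 2)),
               "square")
  expect_error(linear_model(A = matrix(c("-p", "0", "0", "-p"), 2, 2),
                            C = matrix("1", 1, 3)),
               "C has 3 columns")
  expect_error(linear_model(A = matrix("-p", 1, 1), C = matrix("1", 1, 1),
                            parameters = c("p", "p")),
               "duplicate")
  expect_error(linear_model(A = matrix("-s", 1, 1), C = matrix("1", 1, 1)),
               "reserved")
})

test_that("conditions are validated against the model", {
  m <- ex1()$model
  expect_error(validate_ <- linident:::validate_condition(
    m, experiment(x0 = c(1, 2, 3))), "x0 has 3 entries")
  expect_error(linident:::validate_condition(
    m, experiment(x0 = c("p1", 0))), "collide")
  # short x0 pads with zeros
  cond <- linident:::validate_condition(m, experiment(x0 = 5))
  expect_equal(cond$x0[[2]], 0)
})

test_that("every fixture is compartmental: off-diagonal rates are nonnegative", {
  for (id in c(1, 3, 4)) {
    ex <- compartment_example(id)
    An <- linident:::sm_eval(ex$model$A, ex$true_values)
    off <- An - diag(diag(An))
    expect_true(all(off >= 0), label = sprintf("example %d", id))
    # rows sum to at most zero (mass leaves only via elimination)
    expect_true(all(colSums(An) <= 1e-12))
  }
  # examples without printed values: substitute generic positive rates
  for (id in c(2, 5)) {
    ex <- compartment_example(id)
    vals <- stats::setNames(rep(1.5, length(ex$model$parameters)),
                            ex$model$parameters)
    An <- linident:::sm_eval(ex$model$A, vals)
    expect_true(all(An - diag(diag(An)) >= 0))
  }
})

test_that("model spec files round-trip symbolically", {
  ex <- ex1()
  path <- tempfile(fileext = ".yaml")
  write_model_spec(ex$model, path, true_values = ex$true_values,
                   conditions = ex$conditions)
  back <- read_model_spec(path)
  expect_equal(back$model$parameters, ex$model$parameters)
  for (i in 1:2) for (j in 1:2)
    expect_true(linident:::rf_equal(linident:::sm_get(back$model$A, i, j),
                                    linident:::sm_get(ex$model$A, i, j)))
  expect_true(linident:::rf_equal(linident:::sm_get(back$model$C, 1, 1),
                                  linident:::sm_get(ex$model$C, 1, 1)))
  expect_equal(back$true_values[["p3"]], 1.0)
  expect_length(back$conditions, 4)
  # JSON flavour too
  pj <- tempfile(fileext = ".json")
  write_model_spec(ex$model, pj)
  backj <- read_model_spec(pj)
  expect_equal(backj$model$parameters, ex$model$parameters)
})

test_that("random models are reproducible and honour the observation choice", {
  r1 <- random_compartment_model(3, 1, seed = 1)
  r2 <- random_compartment_model(3, 1, seed = 1)
  expect_identical(r1$model$A_chr, r2$model$A_chr)
  expect_identical(r1$true_values, r2$true_values)
  full <- random_compartment_model(2, 2, seed = 0)
  expect_equal(linident:::sm_eval(full$model$C, full$true_values), diag(2))
  expect_error(random_compartment_model(7, 1), "n_y")
})
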