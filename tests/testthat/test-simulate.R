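# Simulation, fitting, scans, and the finite-difference rank oracle.

test_that("simulation reproduces initial outputs and asymptotic decay", {
  ex <- ex1()
  d <- simulate(ex$model, values = ex$true_values,
                condition = ex$conditions$case1, times = c(0, 1, 5, 50))
  expect_equal(d$outputs[1, 1], 15)       # y(0) = x10 / V
  expect_lt(abs(d$outputs[1, 4]), 1e-6)   # stable A: y -> 0 without input
  # eigenvalues at the true rates are negative
  An <- linident:::sm_eval(ex$model$A, ex$true_values)
  expect_true(all(Re(eigen(An)$values) < 0))
  # t = 0 alone returns C x0 + D u0
  d0 <- simulate(ex$model, values = ex$true_values,
                 condition = experiment(x0 = c(3, 1)), times = 0)
  expect_equal(d0$outputs[1, 1], 3)
  expect_error(simulate(ex$model, values = ex$true_values,
                        condition = ex$conditions$case1, times = c(1, 1)),
               "increasing")
  expect_error(simulate(ex$model, values = ex$true_values,
                        condition = experiment(x0 = c("x10", 0)), times = 0:1),
               "numeric")
})

test_that("fitting noise-free data recovers the generating parameters", {
  # simultaneous fit to two datasets resolves the practical correlation
  ex <- ex1()
  tt <- seq(0, 10, length.out = 100)
  d3a <- simulate(ex$model, values = ex$true_values,
                  condition = ex$conditions$case3a, times = tt)
  d3b <- simulate(ex$model, values = ex$true_values,
                  condition = ex$conditions$case3b, times = tt)
  f <- fit_parameters(ex$model, list(d3a, d3b),
                      start = c(p1 = 0.3, p2 = 0.4, p3 = 0.6, p4 = 0.8),
                      fixed = c(V = 1), n_starts = 3)
  expect_true(f$converged)
  expect_equal(unname(f$estimates[RATES1]), c(0.7, 0.7, 1.0, 0.4),
               tolerance = 1e-4)
  # data simulated at the start point is a zero-residual fixed point
  f0 <- fit_parameters(ex$model, d3a,
                       start = ex$true_values[RATES1], fixed = c(V = 1),
                       n_starts = 1)
  expect_lt(f0$residual_norm, 1e-8)
  expect_equal(unname(f0$estimates), unname(ex$true_values[RATES1]),
               tolerance = 1e-6)
  expect_length(residuals(f0), ncol(d3a$outputs))
})

test_that("fixing p1 forces the remaining rates onto the correlation surface", {
  d <- sim1_case1()
  f <- fit_parameters(ex1()$model, d, start = c(p2 = 0.5, p3 = 0.5, p4 = 0.5),
                      fixed = c(p1 = 0.5, V = 1), n_starts = 3)
  # from p1+p2 = 1.4, p2*p3 = 0.7, p3+p4 = 1.4
  expect_equal(unname(f$estimates["p2"]), 0.9, tolerance = 1e-5)
  expect_equal(unname(f$estimates["p3"]), 0.7 / 0.9, tolerance = 1e-5)
  expect_equal(unname(f$estimates["p4"]), 1.4 - 0.7 / 0.9, tolerance = 1e-5)
})

test_that("fully identifiable fixtures are recovered from one dataset", {
  # trap-state model with x3(0) != 0 (all three rates identifiable)
  m2 <- ex2()$model
  tv2 <- c(p21 = 0.9, p12 = 1.4, p13 = 0.6)
  d2 <- simulate(m2, values = tv2, condition = experiment(x0 = c(2, 1, 4), u0 = 2),
                 times = seq(0, 8, length.out = 120))
  f2 <- fit_parameters(m2, d2, start = tv2 * 1.6, n_starts = 3)
  expect_equal(unname(f2$estimates[names(tv2)] / tv2), rep(1, 3),
               tolerance = 1e-4)
  # insulin receptor model observed through total internalized receptor
  ex5b <- ex5(2)
  tv5 <- c(p21u = 1.2, p51 = 0.25, p12 = 0.8, p32 = 1.6,
           p43 = 0.9, p54 = 0.45, p15 = 0.3)
  d5 <- simulate(ex5b$model, values = tv5,
                 condition = ex5b$conditions$standard,
                 times = seq(0, 12, length.out = 120))
  f5 <- fit_parameters(ex5b$model, d5, start = tv5 * 1.3, n_starts = 3)
  expect_equal(unname(f5$estimates[names(tv5)] / tv5), rep(1, 7),
               tolerance = 1e-4)
})

test_that("refit scans stay on the flat zero-residual landscape", {
  d <- sim1_case1()
  # sweep within the feasible interior: p4 = 1.4 - 0.7/(1.4 - p1) > 0
  sc <- correlation_scan(ex1()$model, d, "p1", seq(0.1, 0.85, length.out = 6),
                         start = c(p2 = 0.5, p3 = 0.5, p4 = 0.5),
                         fixed = c(V = 1), n_starts = 1)
  expect_true(all(sc$converged == 1))
  expect_lt(max(sc$residual_norm), 1e-8)
  expect_equal(sc$p2 * sc$p3, rep(0.7, 6), tolerance = 1e-6)
  expect_equal(sc$p1 + sc$p2, rep(1.4, 6), tolerance = 1e-6)
})

test_that("case 2 scan identifies p3 only", {
  ex <- ex1()
  d2 <- simulate(ex$model, values = ex$true_values,
                 condition = ex$conditions$case2,
                 times = seq(0, 10, length.out = 100))
  sc <- correlation_scan(ex$model, d2, "p1", c(0.5, 0.7, 0.9),
                         start = c(p2 = 0.5, p3 = 0.5, p4 = 0.5),
                         fixed = c(V = 1), n_starts = 2)
  expect_equal(sc$p3, rep(1.0, 3), tolerance = 1e-4)
  # p2 moves across the scan: it is genuinely non-identifiable
  expect_gt(diff(range(sc$p2)), 0.05)
})

test_that("finite-difference rank agrees with the symbolic nullspace", {
  ex <- ex1()
  tt <- seq(0, 10, length.out = 60)
  # case 1, all five parameters: nullspace dim 1 -> rank 4
  expect_equal(fd_sensitivity_rank(ex$model, ex$true_values,
                                   ex$conditions$case1, tt), 4L)
  # fully observed two-compartment model: all five identifiable
  full1 <- linear_model(A = ex$model$A_chr, B = ex$model$B_chr, C = diag(2))
  expect_equal(fd_sensitivity_rank(full1, ex$true_values[RATES1],
                                   experiment(x0 = c(15, 5)), tt), 4L)
  # no excitation: rank 0
  expect_equal(fd_sensitivity_rank(ex$model, ex$true_values,
                                   experiment(x0 = c(0, 0)), tt), 0L)
  # four-compartment model driven by a step input: joint nullspace is
  # one-dimensional, so the rank is 6 of 7
  ex4f <- ex4()
  expect_equal(fd_sensitivity_rank(ex4f$model, ex4f$true_values,
                                   ex4f$conditions$fit,
                                   seq(0, 5, length.out = 80)), 6L)
})

with_seed_vals <- function(seed, n) {
  linident:::with_seed(seed * 131, function() round(stats::runif(n, 0.5, 2), 3))
}

test_that("rank agreement holds on seeded random compartment models", {
  for (seed in 1:10) {
    rm <- random_compartment_model(2 + seed %% 3, 1 + seed %% 2, seed = seed)
    m <- rm$model
    numcond <- experiment(x0 = with_seed_vals(seed, m$n_x),
                          u0 = 1.5)
    tt <- seq(0, 6, length.out = 50)
    fd <- fd_sensitivity_rank(m, rm$true_values, numcond, tt)
    sys <- coefficient_system(sensitivity_columns(m, numcond,
                                                  input_mode = "step"))
    M <- linident:::cs_numeric(sys, seed = seed, draws = 1)[[1]]
    expect_equal(fd, linident:::num_rank(M),
                 label = sprintf("random model seed %d", seed))
  }
})
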