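# Identifiable combinations: invariance residuals and the ansatz search.

test_that("invariance residuals certify combinations and reject single parameters", {
  b1 <- rep1_case1()$basis
  expect_true(is_zero_residual(invariance_residual("p2*p3", b1, RATES1)))
  expect_true(is_zero_residual(invariance_residual("p1 + p2", b1, RATES1)))
  # the basis vector is denominator-cleared (scaled by p2), so the
  # directional derivative of the bare parameter p2 is -p2, not zero
  r <- invariance_residual("p2", b1, RATES1)
  expect_false(is_zero_residual(r))
  expect_true(linident:::rf_equal(r[[1]], linident:::as_rf("-p2")))
  expect_error(invariance_residual("p2*q9", b1, RATES1), "outside")
})

test_that("two-compartment search returns the canonical published set", {
  expect_identical(combo_strings(rep1_case1()),
                   sort(c("p1 + p2", "p3 + p4", "p2*p3")))
  # count sanity: group of 4 with a 1-dimensional nullspace -> 3 combinations
  expect_length(rep1_case1()$combinations, 3)
})

test_that("four-compartment search returns the four published combinations", {
  expect_identical(combo_strings(rep4_fit()),
                   sort(c("p03 + p43", "p04 + p24 + p42", "p04*p42", "p24*p43")))
})

test_that("two-path model: degree-3 search spans the published global set", {
  r3 <- rep3_structural()
  got <- r3$combinations
  expect_length(got, 5)
  basis <- r3$basis
  pars <- r3$parameters
  for (cmb in got)
    expect_true(is_zero_residual(invariance_residual(cmb$expression, basis, pars)))
  # the published global combinations satisfy the invariance condition ...
  published <- c(
    "p21 + p31",
    "(p02 + p12)*(p03 + p13)",
    "p02 + p12 + p03 + p13",
    "p03*p31*(p02 + p12) + p02*p21*(p03 + p13)",
    "p31*(p02 + p12 + p03) + p21*(p03 + p13 + p02)")
  for (phi in published)
    expect_true(is_zero_residual(invariance_residual(phi, basis, pars)),
                label = phi)
  # ... and are functionally dependent on the returned generating set
  lp <- asNamespace("linident")
  env <- c(p21 = 1.1, p31 = 1.7, p12 = 0.8, p13 = 1.3, p02 = 0.6, p03 = 1.9)
  base_polys <- lapply(got, `[[`, "poly")
  r0 <- lp$jac_rank(base_polys, pars, env)
  expect_equal(r0, 5)
  for (phi in published) {
    adj <- c(base_polys, list(lp$as_rf(phi)$num))
    expect_equal(lp$jac_rank(adj, pars, env), 5, label = phi)
  }
})

test_that("ansatz cap signals instead of grinding", {
  expect_error(find_combinations(rep3_structural()$basis,
                                 rep3_structural()$parameters,
                                 max_degree = 3, monomial_cap = 10),
               class = "ident_ansatz_cap")
})

test_that("combinations stay constant along a numerical refit scan", {
  sc <- memo("scan1_combo", {
    d <- sim1_case1()
    correlation_scan(ex1()$model, d, "p1", seq(0.2, 0.8, length.out = 5),
                     start = c(p2 = 0.5, p3 = 0.5, p4 = 0.5),
                     fixed = c(V = 1), n_starts = 1)
  })
  for (cmb in rep1_case1()$combinations) {
    vals <- vapply(seq_len(nrow(sc)), function(i) {
      env <- unlist(sc[i, RATES1])
      linident:::lp_eval(cmb$poly, env)
    }, numeric(1))
    expect_lt(max(abs(vals - mean(vals))) / abs(mean(vals)), 1e-4)
  }
})
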