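# Coefficient system, nullspace, groups, classification, dataset counts.

test_that("coefficient system shape and trivial single-parameter case", {
  tiny <- linear_model(A = matrix("-p", 1, 1), C = matrix("1", 1, 1))
  sc <- sensitivity_columns(tiny, experiment(x0 = "x10"))
  sys <- coefficient_system(sc)
  expect_equal(sys$n_cols, 1)
  expect_gte(sys$n_rows, 1)
  expect_false(any(vapply(sys$entries[[1]], linident:::lp_is_zero, logical(1))))
  expect_length(nullspace_basis(sys), 0)   # a single excited parameter is identifiable

  # trap-state model with generic condition: system reduces to rank 2 over
  # 3 unknowns when x30 = 0 (alpha3 free), full rank when x30 != 0
  sysA <- coefficient_system(sensitivity_columns(
    ex2()$model, ex2()$conditions$x30_zero, input_mode = "generic"))
  M <- linident:::cs_numeric(sysA, draws = 1)[[1]]
  expect_equal(linident:::num_rank(M), 2)
  sysB <- coefficient_system(sensitivity_columns(
    ex2()$model, ex2()$conditions$x30_nonzero, input_mode = "generic"))
  MB <- linident:::cs_numeric(sysB, draws = 1)[[1]]
  expect_equal(linident:::num_rank(MB), 3)
})

test_that("two-compartment nullspace vectors match the published relations", {
  # x10 != 0, x20 = 0: alpha = (1, -1, p3/p2, -p3/p2)
  expect_length(rep1_case1()$basis, 1)
  expect_vector_equal(rep1_case1()$basis[[1]],
                      c("1", "-1", "p3/p2", "-p3/p2"))
  # x10 = 0, x20 != 0: alpha3 = 0 and the three-parameter relation
  expect_vector_equal(rep1_case2()$basis[[1]],
                      c("1", "-(p1+p2-p3-p4)/(p1+p2-p4)", "0",
                        "-p3/(p1+p2-p4)"))
  expect_identical(unname(rep1_case2()$status["p3"]), "identifiable")
})

test_that("two-path model nullspace matches the published six-parameter relation", {
  v <- rep3_structural()$basis[[1]]
  expect_vector_equal(v, c("1", "-1", "-p12/p21", "p13/p31",
                           "p12/p21", "-p13/p31"))
  expect_identical(rep3_structural()$group_class, "structural")
})

test_that("structural vs practical classification follows condition dependence", {
  expect_identical(rep1_case1()$group_class, "structural")
  expect_identical(unique(unname(rep1_case1()$status[RATES1])),
                   "structurally-nonidentifiable")
  r3 <- rep1_case3()
  expect_identical(r3$group_class, "practical")
  expect_identical(unique(unname(r3$status)), "practically-nonidentifiable")
  expect_equal(r3$n_max, 4)
  expect_equal(r3$equations_per_dataset, 2)
  expect_equal(r3$n_d, 2)
  expect_equal(required_datasets(r3), 2)
})

test_that("dataset counts: nothing to remedy gives zero", {
  rB <- identifiability(ex2()$model, ex2()$conditions$x30_nonzero,
                        combinations = FALSE)
  expect_length(rB$basis, 0)
  expect_equal(rB$n_d, 0)
  expect_equal(required_datasets(rB), 0)
  expect_equal(linident:::datasets_for_unique_fit(rB), 1L)
})

test_that("stacked rank check certifies when conditions resolve a group", {
  m <- ex1()$model
  c3 <- experiment(x0 = c("a1", "a2"))
  one <- stacked_rank_check(m, list(c3), RATES1)
  expect_false(one$full)
  expect_equal(one$rank, 3)
  two <- stacked_rank_check(m, list(c3, experiment(x0 = c("b1", "b2"))), RATES1)
  expect_true(two$full)
  # two-path model: 2 datasets resolve the 6-parameter group
  m3 <- ex3()$model
  cndA <- experiment(x0 = c("a", "b", "c"), u0 = "u")
  cndB <- experiment(x0 = c("d", "e", "f"), u0 = "w")
  expect_true(stacked_rank_check(m3, list(cndA, cndB), m3$parameters)$full)
  expect_false(stacked_rank_check(m3, list(cndA), m3$parameters)$full)
})

test_that("rank-nullity holds across random numeric draws", {
  sys <- coefficient_system(sensitivity_columns(
    ex1()$model, ex1()$conditions$case3a, parameters = RATES1))
  dim_basis <- length(rep1_case3()$basis)
  for (seed in 1:20) {
    M <- linident:::cs_numeric(sys, seed = seed, draws = 1)[[1]]
    expect_equal(linident:::num_rank(M) + dim_basis, 4)
  }
})

test_that("the basis is invariant under a common polynomial rescaling of the columns", {
  sc <- sensitivity_columns(ex1()$model, ex1()$conditions$case1,
                            parameters = RATES1)
  scaled <- sc
  splus1 <- poly_of("s + 1")
  scaled$columns <- lapply(sc$columns, function(cc)
    lapply(cc, function(p) linident:::lp_mul(p, splus1)))
  scaled$degree_bound <- sc$degree_bound + 1
  b0 <- nullspace_basis(coefficient_system(sc))
  b1 <- nullspace_basis(coefficient_system(scaled))
  expect_length(b1, length(b0))
  expect_vector_equal(b1[[1]], b0[[1]]$strings)
})

test_that("full observation removes every correlation (printed claim)", {
  ex <- ex1()
  full1 <- linear_model(A = ex$model$A_chr, B = ex$model$B_chr,
                        C = diag(2), parameters = RATES1)
  r <- identifiability(full1, experiment(x0 = c("x10", "x20")),
                       combinations = FALSE)
  expect_length(r$basis, 0)
  ex4m <- ex4()$model
  full4 <- linear_model(A = ex4m$A_chr, B = ex4m$B_chr, C = diag(4),
                        parameters = ex4m$parameters)
  r4 <- identifiability(full4, ex4()$conditions$fit, combinations = FALSE)
  expect_length(r4$basis, 0)
})

test_that("stacking conditions can only shrink the nullspace (monotonicity)", {
  m <- ex1()$model
  pv <- stats::setNames(c(0.8, 1.2, 0.9, 1.4, 1), c(RATES1, "V"))
  sv <- seq(0.4, 2.6, length.out = 7)
  blk <- function(x0) linident:::numeric_sensitivity_block(
    m, pv, x0, 0, sv, RATES1)
  B1 <- blk(c(1.7, 0.6)); B2 <- blk(c(0.5, 1.9))
  ns_single <- linident:::num_nullspace(B1)
  ns_stack <- linident:::num_nullspace(rbind(B1, B2))
  # every stacked-nullspace direction is annihilated by the single block
  if (ncol(ns_stack) > 0)
    expect_lt(max(abs(B1 %*% ns_stack)), 1e-8 * max(abs(B1)))
  expect_lte(ncol(ns_stack), ncol(ns_single))
})

test_that("per-output relations recover the single-output correlations of the
           four-compartment model", {
  oc <- output_correlations(ex4()$model, ex4()$conditions$fit)
  y1_groups <- lapply(oc$y1, `[[`, "group")
  expect_true(any(vapply(y1_groups, function(g)
    setequal(g, c("p43", "p03")), logical(1))))
  # q_p43 = q_p03 in the first output, so the dependence weights are (1, -1)
  rel <- oc$y1[[which(vapply(y1_groups, function(g)
    setequal(g, c("p43", "p03")), logical(1)))[1]]]
  idx <- rel$vector$support_idx
  expect_true(linident:::rf_equal(
    rel$vector$entries[[idx[1]]],
    linident:::rf_neg(rel$vector$entries[[idx[2]]])))
})
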