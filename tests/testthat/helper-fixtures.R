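# Shared fixtures and small utilities.  Expensive symbolic analyses are
# memoized so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ex1 <- function() memo("ex1", compartment_example(1))
ex2 <- function() memo("ex2", compartment_example(2))
ex3 <- function() memo("ex3", compartment_example(3))
ex4 <- function() memo("ex4", compartment_example(4))
ex5 <- function(out = 1) memo(paste0("ex5_", out), compartment_example(5, outputs = out))

RATES1 <- c("p1", "p2", "p3", "p4")

rep1_case1 <- function() memo("rep1_case1",
  identifiability(ex1()$model, ex1()$conditions$case1, parameters = RATES1))
rep1_case2 <- function() memo("rep1_case2",
  identifiability(ex1()$model, ex1()$conditions$case2, parameters = RATES1))
rep1_case3 <- function() memo("rep1_case3",
  identifiability(ex1()$model, ex1()$conditions$case3a, parameters = RATES1,
                  combinations = FALSE))
rep3_structural <- function() memo("rep3_structural",
  identifiability(ex3()$model, ex3()$conditions$structural, max_degree = 3))
rep4_fit <- function() memo("rep4_fit",
  identifiability(ex4()$model, ex4()$conditions$fit, max_degree = 2))
rep5_y1 <- function() memo("rep5_y1",
  identifiability(ex5(1)$model, ex5(1)$conditions$standard, combinations = FALSE))

sim1_case1 <- function(n = 100) memo(paste0("sim1_case1_", n),
  simulate(ex1()$model, values = ex1()$true_values,
           condition = ex1()$conditions$case1,
           times = seq(0, 10, length.out = n)))

# symbolic equality of a basis vector against expected expression strings
expect_vector_equal <- function(v, expected) {
  expect_length(v$entries, length(expected))
  for (i in seq_along(expected)) {
    e <- linident:::as_rf(expected[i])
    expect_true(linident:::rf_equal(v$entries[[i]], e),
                label = sprintf("entry %d: %s vs %s", i, v$strings[i], expected[i]))
  }
}

combo_strings <- function(report) {
  sort(vapply(report$combinations, `[[`, character(1), "expression"))
}

# parse a polynomial string into the internal exact representation
poly_of <- function(txt) linident:::as_rf(txt)$num
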