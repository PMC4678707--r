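#' Define a linear time-invariant state-space model
#'
#' Builds the model \eqn{\dot x = A x + B u}, \eqn{y = C x + D u} whose
#' matrix entries are arithmetic expressions in named rate parameters.
#' Parameters are inferred as the set of free symbols appearing in the
#' matrices; an explicit \code{parameters} argument overrides the inferred
#' order (it must contain every inferred symbol).
#'
#' @param A state matrix (\code{n_x} by \code{n_x}), as a character matrix of
#'   expressions (e.g. \code{"-(p1+p2)"}) or a numeric matrix.
#' @param C output matrix (\code{n_y} by \code{n_x}), same conventions.
#' @param B input matrix (\code{n_x} by \code{n_u}); defaults to a single
#'   zero input column.
#' @param D feedthrough matrix (\code{n_y} by \code{n_u}); defaults to zero.
#' @param states,inputs,outputs optional name vectors; defaults
#'   \code{x1..}, \code{u1..}, \code{y1..}.
#' @param parameters optional character vector fixing the parameter order.
#' @param name model label used in printing and reports.
#' @return An object of class \code{"linear_model"}.
#' @examples
#' m <- linear_model(
#'   A = matrix(c("-(p1+p2)", "p2", "p3", "-(p3+p4)"), 2, 2),
#'   B = matrix(c("1", "0"), 2, 1),
#'   C = matrix(c("1/V", "0"), 1, 2))
#' m
#' @export
linear_model <- function(A, C, B = NULL, D = NULL,
                         states = NULL, inputs = NULL, outputs = NULL,
                         parameters = NULL, name = "model") {
  A <- coerce_exprmat(A, "A")
  C <- coerce_exprmat(C, "C")
  n_x <- nrow(A)
  if (ncol(A) != n_x)
    stop("matrix A must be square", call. = FALSE)
  if (ncol(C) != n_x)
    stop(sprintf("matrix C has %d columns but the model has %d states",
                 ncol(C), n_x), call. = FALSE)
  n_y <- nrow(C)
  if (is.null(B)) B <- matrix("0", n_x, 1)
  B <- coerce_exprmat(B, "B")
  if (nrow(B) != n_x)
    stop(sprintf("matrix B has %d rows but the model has %d states",
                 nrow(B), n_x), call. = FALSE)
  n_u <- ncol(B)
  if (is.null(D)) D <- matrix("0", n_y, n_u)
  D <- coerce_exprmat(D, "D")
  if (nrow(D) != n_y || ncol(D) != n_u)
    stop(sprintf("matrix D must be %d by %d", n_y, n_u), call. = FALSE)

  mats <- list(A = sm_from_char(A), B = sm_from_char(B),
               C = sm_from_char(C), D = sm_from_char(D))
  syms <- sort(unique(unlist(lapply(mats, function(m)
    unlist(lapply(m, rf_vars))))))
  if ("s" %in% syms)
    stop("'s' is reserved for the Laplace variable and cannot be a parameter",
         call. = FALSE)
  if (is.null(parameters)) {
    parameters <- syms
  } else {
    if (anyDuplicated(parameters))
      stop("duplicate parameter names", call. = FALSE)
    missing <- setdiff(syms, parameters)
    if (length(missing))
      stop(sprintf("symbols appear in the matrices but not in 'parameters': %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(parameters) < 1)
    stop("the model must contain at least one parameter", call. = FALSE)

  if (is.null(states)) states <- paste0("x", seq_len(n_x))
  if (is.null(inputs)) inputs <- paste0("u", seq_len(n_u))
  if (is.null(outputs)) outputs <- paste0("y", seq_len(n_y))
  stopifnot(length(states) == n_x, length(inputs) == n_u,
            length(outputs) == n_y)

  # which parameters appear in each matrix (ordering p_A, p_B, p_C, p_D)
  in_mat <- lapply(mats, function(m)
    intersect(parameters, unique(unlist(lapply(m, rf_vars)))))

  structure(list(name = name, A = mats$A, B = mats$B, C = mats$C, D = mats$D,
                 A_chr = A, B_chr = B, C_chr = C, D_chr = D,
                 states = states, inputs = inputs, outputs = outputs,
                 parameters = parameters, param_blocks = in_mat,
                 n_x = n_x, n_y = n_y, n_u = n_u),
            class = "linear_model")
}

coerce_exprmat <- function(m, label) {
  # YAML/JSON loaders collapse single-column matrices to plain vectors
  if (!is.matrix(m) && is.atomic(m) && length(m) >= 1)
    m <- matrix(m, ncol = 1)
  if (is.numeric(m)) {
    m2 <- matrix(vapply(m, function(v)
      format(v, scientific = FALSE, trim = TRUE, digits = 15), character(1)),
      nrow(m), ncol(m))
    return(m2)
  }
  if (is.list(m) && !is.matrix(m)) {
    # list of rows (as parsed from YAML/JSON)
    rows <- lapply(m, function(r) vapply(r, as.character, character(1)))
    nc <- unique(vapply(rows, length, numeric(1)))
    if (length(nc) != 1)
      stop(sprintf("ragged rows in matrix %s", label), call. = FALSE)
    return(matrix(unlist(rows), length(rows), nc, byrow = TRUE))
  }
  if (is.matrix(m) && is.character(m)) return(m)
  stop(sprintf("matrix %s must be numeric or character", label), call. = FALSE)
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("Linear state-space model '%s' (%d states, %d outputs, %d inputs, %d parameters)\n",
              x$name, x$n_x, x$n_y, x$n_u, length(x$parameters)))
  for (i in seq_len(x$n_x)) {
    terms <- character(0)
    for (j in seq_len(x$n_x)) {
      e <- sm_get(x$A, i, j)
      if (!rf_is_zero(e)) terms <- c(terms, paste0("(", rf_to_string(e), ")*", x$states[j]))
    }
    for (k in seq_len(x$n_u)) {
      e <- sm_get(x$B, i, k)
      if (!rf_is_zero(e)) terms <- c(terms, paste0("(", rf_to_string(e), ")*", x$inputs[k]))
    }
    if (length(terms) == 0) terms <- "0"
    cat(sprintf("  d%s/dt = %s\n", x$states[i], paste(terms, collapse = " + ")))
  }
  for (i in seq_len(x$n_y)) {
    terms <- character(0)
    for (j in seq_len(x$n_x)) {
      e <- sm_get(x$C, i, j)
      if (!rf_is_zero(e)) terms <- c(terms, paste0("(", rf_to_string(e), ")*", x$states[j]))
    }
    for (k in seq_len(x$n_u)) {
      e <- sm_get(x$D, i, k)
      if (!rf_is_zero(e)) terms <- c(terms, paste0("(", rf_to_string(e), ")*", x$inputs[k]))
    }
    if (length(terms) == 0) terms <- "0"
    cat(sprintf("  %s = %s\n", x$outputs[i], paste(terms, collapse = " + ")))
  }
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Define an experiment condition
#'
#' An experiment is an initial state vector together with constant control
#' values.  Each entry may be a number, the name of a free symbol (for a
#' generic nonzero value), or zero.  Unspecified initial states default to
#' zero.
#'
#' @param x0 initial state vector; numeric values, symbol names, or 0.
#' @param u0 constant control vector; same conventions.  Defaults to zero
#'   controls.
#' @return An object of class \code{"experiment"}.
#' @examples
#' experiment(x0 = c(15, 0))
#' experiment(x0 = c("x10", 0), u0 = "u1")
#' @export
experiment <- function(x0, u0 = NULL) {
  x0 <- lapply(x0, norm_entry)
  u0 <- if (is.null(u0)) list() else lapply(u0, norm_entry)
  structure(list(x0 = x0, u0 = u0), class = "experiment")
}

norm_entry <- function(e) {
  if (is.numeric(e)) return(unname(e))
  if (is.character(e)) {
    if (grepl("^[+-]?[0-9.]+$", e)) return(as.numeric(e))
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", e))
      stop(sprintf("condition entry '%s' is neither a number nor a symbol name", e),
           call. = FALSE)
    return(e)
  }
  stop("condition entries must be numeric or character", call. = FALSE)
}

#' @export
print.experiment <- function(x, ...) {
  fmt <- function(v) vapply(v, function(e) as.character(e), character(1))
  cat("Experiment condition\n")
  cat("  x0 =", paste(fmt(x$x0), collapse = ", "), "\n")
  if (length(x$u0))
    cat("  u0 =", paste(fmt(x$u0), collapse = ", "), "\n")
  invisible(x)
}

# pad/validate a condition against a model
validate_condition <- function(model, cond) {
  if (!inherits(cond, "experiment"))
    stop("condition must be created with experiment()", call. = FALSE)
  x0 <- cond$x0; u0 <- cond$u0
  if (length(x0) < model$n_x)
    x0 <- c(x0, as.list(rep(0, model$n_x - length(x0))))
  if (length(x0) != model$n_x)
    stop(sprintf("x0 has %d entries but the model has %d states",
                 length(cond$x0), model$n_x), call. = FALSE)
  if (length(u0) < model$n_u)
    u0 <- c(u0, as.list(rep(0, model$n_u - length(u0))))
  if (length(u0) != model$n_u)
    stop(sprintf("u0 has %d entries but the model has %d inputs",
                 length(cond$u0), model$n_u), call. = FALSE)
  syms <- c(Filter(is.character, x0), Filter(is.character, u0))
  bad <- intersect(unlist(syms), model$parameters)
  if (length(bad))
    stop(sprintf("condition symbols collide with model parameters: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if ("s" %in% unlist(syms))
    stop("'s' is reserved for the Laplace variable", call. = FALSE)
  structure(list(x0 = x0, u0 = u0), class = "experiment")
}

cond_is_numeric <- function(cond) {
  all(vapply(c(cond$x0, cond$u0), is.numeric, logical(1)))
}

cond_numeric <- function(model, cond) {
  cond <- validate_condition(model, cond)
  if (!cond_is_numeric(cond))
    stop("this operation needs a fully numeric experiment condition",
         call. = FALSE)
  list(x0 = vapply(cond$x0, as.numeric, numeric(1)),
       u0 = vapply(cond$u0, as.numeric, numeric(1)))
}

# replace every nonzero entry by a generic free symbol (x10-style names),
# keeping user-supplied symbols; returns the condition plus the symbol list
cond_genericize <- function(model, cond) {
  cond <- validate_condition(model, cond)
  syms <- character(0)
  gx <- vector("list", model$n_x)
  for (i in seq_len(model$n_x)) {
    e <- cond$x0[[i]]
    if (is.numeric(e) && e == 0) { gx[[i]] <- 0; next }
    nm <- if (is.character(e)) e else paste0("x", i, "0")
    if (nm %in% model$parameters)
      nm <- paste0(nm, "_ic")
    gx[[i]] <- nm; syms <- c(syms, nm)
  }
  gu <- vector("list", model$n_u)
  for (k in seq_len(model$n_u)) {
    e <- cond$u0[[k]]
    if (is.numeric(e) && e == 0) { gu[[k]] <- 0; next }
    nm <- if (is.character(e)) e else paste0("u", k, "c")
    if (nm %in% model$parameters)
      nm <- paste0(nm, "_in")
    gu[[k]] <- nm; syms <- c(syms, nm)
  }
  list(cond = structure(list(x0 = gx, u0 = gu), class = "experiment"),
       symbols = syms)
}

# run a function with a temporary RNG state
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# ------------------------------------------------------------------------
# built-in compartment-model fixtures

#' Built-in compartment model examples
#'
#' Five classic partially observed linear compartment models, each bundled
#' with the experiment conditions analyzed in the identifiability literature
#' and, where published, the true parameter values used for numerical
#' verification.  Example 5 is a five-compartment insulin receptor
#' trafficking model in which the bilinear term \eqn{p_{21} u} (constant
#' insulin input) is absorbed into the single rate parameter \code{p21u};
#' this aliasing is recorded in the returned \code{notes}.
#'
#' @param id integer 1 to 5.
#' @param outputs for \code{id = 5}, which of the three measured mixtures to
#'   observe: subsets of \code{1:3} (y1 = x3+x4 total phosphorylated IR,
#'   y2 = x4+x5 total internalized IR, y3 = x2+x3 total surface IR).
#' @return A list with components \code{model} (a \code{linear_model}),
#'   \code{conditions} (named list of \code{experiment} objects),
#'   \code{true_values} (named numeric, possibly empty),
#'   \code{estimated} (the parameters the published case analysis estimates),
#'   and \code{notes}.
#' @examples
#' ex <- compartment_example(1)
#' ex$model
#' names(ex$conditions)
#' @export
compartment_example <- function(id, outputs = 1) {
  id <- as.integer(id)
  if (is.na(id) || id < 1 || id > 5)
    stop("example id must be 1..5", call. = FALSE)
  switch(id, ex_two_compartment(), ex_three_compartment_da(),
         ex_three_compartment_full(), ex_four_compartment(),
         ex_insulin_receptor(outputs))
}

ex_two_compartment <- function() {
  m <- linear_model(
    A = matrix(c("-(p1+p2)", "p2", "p3", "-(p3+p4)"), 2, 2),
    B = matrix(c("1", "0"), 2, 1),
    C = matrix(c("1/V", "0"), 1, 2),
    name = "two-compartment")
  list(model = m,
       conditions = list(
         case1 = experiment(x0 = c(15, 0)),
         case2 = experiment(x0 = c(0, 15)),
         case3a = experiment(x0 = c(15, 5)),
         case3b = experiment(x0 = c(5, 15))),
       true_values = c(p1 = 0.7, p2 = 0.7, p3 = 1.0, p4 = 0.4, V = 1.0),
       estimated = c("p1", "p2", "p3", "p4"),
       notes = paste("The published case analysis estimates the four rate",
                     "parameters with the observation volume V known."))
}

ex_three_compartment_da <- function() {
  m <- linear_model(
    A = matrix(c("-p21", "p21", "0",
                 "p12", "-p12", "0",
                 "p13", "0", "-p13"), 3, 3),
    B = matrix(c("1", "0", "0"), 3, 1),
    C = matrix(c("0", "1", "0"), 1, 3),
    name = "three-compartment (trap state)")
  list(model = m,
       conditions = list(
         x30_zero = experiment(x0 = c("x10", "x20", 0), u0 = "uc"),
         x30_nonzero = experiment(x0 = c("x10", "x20", "x30"), u0 = "uc")),
       true_values = numeric(0),
       estimated = m$parameters,
       notes = paste("Known failure case for differential-algebra",
                     "identifiability tests when x3(0) = 0."))
}

ex_three_compartment_full <- function() {
  m <- linear_model(
    A = matrix(c("-(p21+p31)", "p21", "p31",
                 "p12", "-(p12+p02)", "0",
                 "p13", "0", "-(p13+p03)"), 3, 3),
    B = matrix(c("1", "0", "0"), 3, 1),
    C = matrix(c("1", "0", "0"), 1, 3),
    parameters = c("p21", "p31", "p12", "p13", "p02", "p03"),
    name = "three-compartment (two elimination paths)")
  list(model = m,
       conditions = list(
         fit = experiment(x0 = c(0, 0, 0), u0 = 25),
         structural = experiment(x0 = c("x10", 0, 0), u0 = "uc"),
         remedy = experiment(x0 = c("x10", "x20", "x30"), u0 = "uc")),
       true_values = c(p02 = 2, p12 = 3, p03 = 3, p13 = 0.4, p21 = 1, p31 = 2),
       estimated = m$parameters,
       notes = "")
}

ex_four_compartment <- function() {
  m <- linear_model(
    A = matrix(c("-p31", "0", "p31", "0",
                 "0", "-p42", "0", "p42",
                 "p13", "0", "-(p03+p13+p43)", "p43",
                 "0", "p24", "0", "-(p04+p24)"), 4, 4),
    B = matrix(c("1", "0", "0", "0"), 4, 1),
    C = matrix(c("1", "0",
                 "0", "1",
                 "0", "0",
                 "0", "0"), 2, 4),
    parameters = c("p31", "p13", "p42", "p24", "p43", "p03", "p04"),
    name = "four-compartment")
  list(model = m,
       conditions = list(
         fit = experiment(x0 = c(0, 0, 0, 0), u0 = 5),
         remedy = experiment(x0 = c("x10", "x20", "x30", "x40"), u0 = "uc")),
       true_values = c(p31 = 3.0, p13 = 5.5, p03 = 1.0, p04 = 0.7,
                       p24 = 3.5, p42 = 3.0, p43 = 4.0),
       estimated = m$parameters,
       notes = "")
}

ex_insulin_receptor <- function(outputs = 1) {
  outputs <- sort(unique(as.integer(outputs)))
  if (length(outputs) == 0 || any(!outputs %in% 1:3))
    stop("example 5 outputs must be a subset of 1:3", call. = FALSE)
  crows <- list(c("0", "0", "1", "1", "0"),   # y1 = x3 + x4
                c("0", "0", "0", "1", "1"),   # y2 = x4 + x5
                c("0", "1", "1", "0", "0"))   # y3 = x2 + x3
  C <- do.call(rbind, crows[outputs])
  m <- linear_model(
    A = matrix(c("-(p21u+p51)", "p21u", "0", "0", "p51",
                 "p12", "-(p12+p32)", "p32", "0", "0",
                 "0", "0", "-p43", "p43", "0",
                 "0", "0", "0", "-p54", "p54",
                 "p15", "0", "0", "0", "-p15"), 5, 5),
    C = C,
    outputs = paste0("y", outputs),
    parameters = c("p21u", "p51", "p12", "p32", "p43", "p54", "p15"),
    name = "insulin-receptor")
  list(model = m,
       conditions = list(standard = experiment(x0 = c(100, 0, 0, 0, 0))),
       true_values = numeric(0),
       estimated = m$parameters,
       notes = paste("p21u absorbs the bilinear term p21*u for the constant",
                     "insulin input u; with u known, p21 = p21u / u."))
}

# ------------------------------------------------------------------------

#' Generate a random compartment-style test model
#'
#' Draws a sparse first-order exchange network on \code{n_x} pools with one
#' rate parameter per transfer, a single input into pool 1, and an output
#' matrix selecting \code{observed_states}.  Used for property-based testing
#' of the correlation analysis against numerical rank oracles.
#'
#' @param n_x number of states (at most 6).
#' @param n_y number of observed states.
#' @param observed_states which states are measured (default the first
#'   \code{n_y}).
#' @param seed integer seed; the same seed always returns the same model.
#' @return list with \code{model}, \code{true_values}, and a generic
#'   all-nonzero \code{condition}.
#' @export
random_compartment_model <- function(n_x, n_y, observed_states = NULL,
                                     seed = 1) {
  if (!(n_y >= 1 && n_y <= n_x && n_x <= 6))
    stop("need 1 <= n_y <= n_x <= 6", call. = FALSE)
  if (is.null(observed_states)) observed_states <- seq_len(n_y)
  stopifnot(length(observed_states) == n_y, all(observed_states %in% seq_len(n_x)))
  with_seed(seed, function() {
    A <- matrix("0", n_x, n_x)
    pnames <- character(0)
    # guarantee a spanning chain 1 -> 2 -> ... -> n_x, then sprinkle extras
    edges <- cbind(seq_len(n_x - 1), seq_len(n_x - 1) + 1)
    for (i in seq_len(n_x)) for (j in seq_len(n_x)) {
      if (i == j) next
      if (any(edges[, 1] == j & edges[, 2] == i)) next
      if (stats::runif(1) < 0.3) edges <- rbind(edges, c(j, i))
    }
    diag_terms <- rep("", n_x)
    for (r in seq_len(nrow(edges))) {
      from <- edges[r, 1]; to <- edges[r, 2]
      p <- paste0("p", to, from)
      A[to, from] <- p
      diag_terms[from] <- paste0(diag_terms[from], "+", p)
      pnames <- c(pnames, p)
    }
    # elimination from a random pool keeps A Hurwitz-like and adds a column sum
    out_pool <- sample.int(n_x, 1)
    p0 <- paste0("p0", out_pool)
    diag_terms[out_pool] <- paste0(diag_terms[out_pool], "+", p0)
    pnames <- c(pnames, p0)
    for (i in seq_len(n_x))
      A[i, i] <- if (nzchar(diag_terms[i])) paste0("-(", sub("^\\+", "", diag_terms[i]), ")") else "0"
    B <- matrix("0", n_x, 1); B[1, 1] <- "1"
    C <- matrix("0", n_y, n_x)
    for (k in seq_along(observed_states)) C[k, observed_states[k]] <- "1"
    m <- linear_model(A = A, B = B, C = C, name = sprintf("random-%d", seed))
    vals <- stats::runif(length(m$parameters), 0.5, 2.0)
    names(vals) <- m$parameters
    cond <- experiment(x0 = paste0("x", seq_len(n_x), "0"), u0 = "uc")
    list(model = m, true_values = vals, condition = cond)
  })
}
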