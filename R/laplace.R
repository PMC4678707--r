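# Laplace-domain sensitivity construction.
#
# For x' = Ax + Bu, y = Cx + Du with x(0) = x0 and constant controls, the
# state transform is X(s) = (sI-A)^{-1} (B U(s) + x0) and the output
# sensitivity to a parameter p splits into four blocks:
#     dY/dp_A = C (sI-A)^{-1} (dA/dp) X(s)
#     dY/dp_B = C (sI-A)^{-1} (dB/dp) U(s)
#     dY/dp_C = (dC/dp) X(s)
#     dY/dp_D = (dD/dp) U(s)
# The inverse is taken as adjugate/Delta with Delta = det(sI-A), so every
# block sits over the single polynomial denominator s^m * Delta^2 (m = 1
# when step inputs u0/s are present) and the numerators stay polynomial.
# Linear dependence among columns is invariant under this common scaling.

LAPLACE_VAR <- "s"

sI_minus_A <- function(model) {
  n <- model$n_x
  out <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- rf_neg(sm_get(model$A, i, j))
    if (i == j) e <- rf_add(e, rf_from_poly(lp_var(LAPLACE_VAR)))
    out[[i + (j - 1) * n]] <- e
  }
  sm_matrix(out, n, n)
}

#' Characteristic polynomial of a linear model
#'
#' Returns \eqn{\Delta = \det(sI - A)}, the common denominator of all
#' Laplace-domain state solutions, as a symbolic expression in \code{s} and
#' the model parameters (monic of degree \code{n_x}).
#'
#' @param model a \code{linear_model}.
#' @return a symbolic rational expression (class \code{"lrf"}); use
#'   \code{format()} or \code{print()} to display it.
#' @examples
#' ex <- compartment_example(1)
#' characteristic_polynomial(ex$model)
#' @export
characteristic_polynomial <- function(model) {
  sm_det(sI_minus_A(model))
}

#' @export
format.lrf <- function(x, ...) rf_to_string(x)

# condition entry -> rf (numbers become exact rationals, names become symbols)
entry_rf <- function(e) {
  if (is.numeric(e)) as_rf(e) else rf_from_poly(lp_var(e))
}

#' Laplace-domain state solution
#'
#' Solves the state equation in the Laplace domain,
#' \eqn{X(s) = (sI-A)^{-1}(B U(s) + x_0)}, returning the numerator vector
#' over the cleared common denominator.  With \code{input_mode = "step"}
#' constant controls enter as \eqn{U_i(s) = u_{0i}/s} and the denominator is
#' \eqn{s\,\Delta}; with \code{input_mode = "generic"} each control is an
#' indeterminate constant and the denominator is \eqn{\Delta}.
#'
#' @param model a \code{linear_model}.
#' @param condition an \code{experiment}.
#' @param input_mode \code{"generic"} or \code{"step"}.
#' @return list with \code{X_num} (list of symbolic numerators),
#'   \code{Delta}, \code{den} (the full denominator including any input
#'   clearing factor \code{s^m}), and \code{m}.
#' @export
laplace_state <- function(model, condition, input_mode = c("generic", "step")) {
  input_mode <- match.arg(input_mode)
  cond <- validate_condition(model, condition)
  Ms <- sI_minus_A(model)
  Delta <- sm_det(Ms)
  adj <- sm_adjugate(Ms)
  u_rf <- lapply(cond$u0, entry_rf)
  anyu <- any(!vapply(u_rf, rf_is_zero, logical(1)))
  m <- if (input_mode == "step" && anyu) 1L else 0L
  x_rf <- lapply(cond$x0, entry_rf)
  if (m == 1L) {
    spoly <- rf_from_poly(lp_var(LAPLACE_VAR))
    x_rf <- lapply(x_rf, function(e) rf_mul(e, spoly))
  }
  rhs_list <- vector("list", model$n_x)
  for (i in seq_len(model$n_x)) {
    acc <- x_rf[[i]]
    for (k in seq_len(model$n_u)) {
      b <- sm_get(model$B, i, k)
      if (!rf_is_zero(b) && !rf_is_zero(u_rf[[k]]))
        acc <- rf_add(acc, rf_mul(b, u_rf[[k]]))
    }
    rhs_list[[i]] <- acc
  }
  rhs <- sm_matrix(rhs_list, model$n_x, 1)
  Xnum <- sm_mul(adj, rhs)
  den <- Delta
  if (m == 1L) den <- rf_mul(den, rf_from_poly(lp_var(LAPLACE_VAR)))
  list(X_num = as.list(Xnum), Delta = Delta, den = den, m = m,
       adj = adj, U = u_rf, cond = cond, input_mode = input_mode)
}

#' Partial derivative matrices of the four model blocks
#'
#' Returns the matrices \eqn{M_A = \partial(AX)/\partial p_A},
#' \eqn{M_B = \partial(BU)/\partial p_B}, \eqn{M_C = \partial(CX)/\partial
#' p_C}, \eqn{M_D = \partial(DU)/\partial p_D} with the state transforms
#' written as formal symbols \code{X1, X2, ...} and the inputs as
#' \code{U1, ...}; blocks without parameters have zero columns.
#'
#' @param model a \code{linear_model}.
#' @return list of four character matrices (columns labelled by parameter).
#' @examples
#' derivative_matrices(compartment_example(1)$model)$M_A
#' @export
derivative_matrices <- function(model) {
  Xs <- lapply(seq_len(model$n_x), function(i) rf_from_poly(lp_var(paste0("X", i))))
  Us <- lapply(seq_len(model$n_u), function(k) rf_from_poly(lp_var(paste0("U", k))))
  block <- function(M, vec, nrow_out, pars) {
    if (length(pars) == 0)
      return(matrix(character(0), nrow_out, 0))
    out <- matrix("0", nrow_out, length(pars), dimnames = list(NULL, pars))
    for (jj in seq_along(pars)) {
      p <- pars[jj]
      for (i in seq_len(nrow_out)) {
        acc <- rf_zero()
        for (k in seq_along(vec)) {
          e <- sm_get(M, i, k)
          de <- rf_deriv(e, p)
          if (!rf_is_zero(de)) acc <- rf_add(acc, rf_mul(de, vec[[k]]))
        }
        out[i, jj] <- rf_to_string(acc)
      }
    }
    out
  }
  list(M_A = block(model$A, Xs, model$n_x, model$param_blocks$A),
       M_B = block(model$B, Us, model$n_x, model$param_blocks$B),
       M_C = block(model$C, Xs, model$n_y, model$param_blocks$C),
       M_D = block(model$D, Us, model$n_y, model$param_blocks$D))
}

rf_deriv <- function(a, v) {
  if (rf_den_is_one(a)) return(rf_from_poly(lp_deriv(a$num, v)))
  # quotient rule
  rf_simplify(rf_make(
    lp_sub(lp_mul(lp_deriv(a$num, v), a$den), lp_mul(a$num, lp_deriv(a$den, v))),
    lp_mul(a$den, a$den)))
}

#' Symbolic output sensitivity columns
#'
#' Assembles, for each estimated parameter, the polynomial column vector
#' \eqn{q_j(s)} of output sensitivities over the cleared common denominator,
#' and divides out any polynomial factor common to every entry (linear
#' dependence among columns is unchanged by a common nonzero scaling).
#'
#' @param model a \code{linear_model}.
#' @param condition an \code{experiment}; nonzero entries are treated as
#'   generic symbols during the symbolic analysis.
#' @param parameters the parameters under estimation (default all); the
#'   rest are treated as known constants.
#' @param input_mode \code{"generic"} treats each constant control as a free
#'   symbol (the usual analysis convention); \code{"step"} uses the literal
#'   step transform \eqn{u_0/s}.
#' @param cancel divide out the global polynomial common factor.
#' @param genericize replace nonzero numeric condition entries by symbols
#'   (the default for analysis).
#' @return object of class \code{"sensitivity_columns"}: \code{columns} is a
#'   list (one per parameter) of lists of polynomial entries (one per
#'   output); also \code{param_order}, \code{degree_bound}, \code{denom}
#'   description, \code{condition_symbols}.
#' @examples
#' ex <- compartment_example(1)
#' sc <- sensitivity_columns(ex$model, ex$conditions$case1,
#'                           parameters = c("p1", "p2", "p3", "p4"))
#' sc
#' @export
sensitivity_columns <- function(model, condition,
                                parameters = model$parameters,
                                input_mode = c("generic", "step"),
                                cancel = TRUE, genericize = TRUE) {
  input_mode <- match.arg(input_mode)
  stopifnot(all(parameters %in% model$parameters))
  if (genericize) {
    g <- cond_genericize(model, condition)
    cond <- g$cond; cond_syms <- g$symbols
  } else {
    cond <- validate_condition(model, condition)
    cond_syms <- unlist(Filter(is.character, c(cond$x0, cond$u0)))
  }
  ls <- laplace_state(model, cond, input_mode)
  Delta <- ls$Delta
  adj <- ls$adj
  Xnum <- sm_matrix(ls$X_num, model$n_x, 1)
  Uvec <- sm_matrix(ls$U, model$n_u, 1)
  Delta2 <- rf_mul(Delta, Delta)

  # every block is expressed over the common denominator s^m * Delta^2
  cols <- vector("list", length(parameters))
  names(cols) <- parameters
  for (jj in seq_along(parameters)) {
    p <- parameters[jj]
    acc <- replicate(model$n_y, rf_zero(), simplify = FALSE)
    if (p %in% model$param_blocks$A) {
      dA <- sm_apply(model$A, function(e) rf_deriv(e, p))
      v <- sm_mul(model$C, sm_mul(adj, sm_mul(dA, Xnum)))
      acc <- Map(rf_add, acc, as.list(v))
    }
    if (p %in% model$param_blocks$B) {
      # ls$U holds the input numerators over s^m, so this block sits over
      # s^m * Delta; one factor Delta brings it to the common scale
      dB <- sm_apply(model$B, function(e) rf_deriv(e, p))
      v <- sm_mul(model$C, sm_mul(adj, sm_mul(dB, Uvec)))
      v <- sm_apply(v, function(e) rf_mul(e, Delta))
      acc <- Map(rf_add, acc, as.list(v))
    }
    if (p %in% model$param_blocks$C) {
      dC <- sm_apply(model$C, function(e) rf_deriv(e, p))
      v <- sm_mul(dC, Xnum)
      v <- sm_apply(v, function(e) rf_mul(e, Delta))
      acc <- Map(rf_add, acc, as.list(v))
    }
    if (p %in% model$param_blocks$D) {
      dD <- sm_apply(model$D, function(e) rf_deriv(e, p))
      v <- sm_mul(dD, Uvec)
      v <- sm_apply(v, function(e) rf_mul(e, Delta2))
      acc <- Map(rf_add, acc, as.list(v))
    }
    cols[[jj]] <- acc
  }

  # clear any residual rational-function denominators to one common
  # polynomial (handles parameters in C like 1/V and step-input 1/s factors)
  dens <- list()
  for (cc in cols) for (e in cc)
    if (!rf_is_zero(e) && !rf_den_is_one(e)) dens <- c(dens, list(e$den))
  if (length(dens)) {
    common <- lp_const(1)
    for (d in dens) {
      g <- lp_gcd(common, d)
      common <- lp_divexact(lp_mul(common, d), g)
    }
    cols <- lapply(cols, function(cc) lapply(cc, function(e) {
      if (rf_is_zero(e)) return(e)
      rf_from_poly(lp_mul(e$num, lp_divexact(common, e$den)))
    }))
  }
  ents <- lapply(unlist(cols, recursive = FALSE), function(e) e$num)
  if (all(vapply(ents, lp_is_zero, logical(1))))
    stop_no_excitation()

  cancelled <- lp_const(1)
  if (cancel) {
    g <- lp_gcd_list(ents)
    if (!lp_is_const(g) && !lp_is_zero(g)) {
      cols <- lapply(cols, function(cc) lapply(cc, function(e) {
        if (rf_is_zero(e)) e else rf_from_poly(lp_divexact(e$num, g))
      }))
      cancelled <- g
    }
  }
  # deterministic collective normalization: first nonzero entry primitive
  polys <- lapply(cols, function(cc) lapply(cc, function(e) e$num))
  first <- NULL
  for (cc in polys) for (e in cc) if (!lp_is_zero(e) && is.null(first)) first <- e
  pr <- lp_primitive(first)
  sc_num <- first$den[1] * pr$num[1]
  sc_den <- first$num[1] * pr$den[1]
  polys <- lapply(polys, function(cc) lapply(cc, function(e)
    if (lp_is_zero(e)) e else lp_scale(e, sc_num, sc_den)))

  degree_bound <- max(vapply(unlist(polys, recursive = FALSE),
                             lp_degree, numeric(1), v = LAPLACE_VAR))
  structure(list(columns = polys, param_order = parameters,
                 n_y = model$n_y, outputs = model$outputs,
                 degree_bound = degree_bound,
                 Delta = Delta, m = ls$m,
                 input_mode = input_mode,
                 cancelled = lp_to_string(cancelled),
                 condition_symbols = cond_syms,
                 condition = cond,
                 param_blocks = model$param_blocks,
                 n_x = model$n_x),
            class = "sensitivity_columns")
}

stop_no_excitation <- function() {
  stop(structure(class = c("ident_no_excitation", "error", "condition"),
                 list(message = paste("all sensitivity columns are zero:",
                                      "the condition provides no excitation",
                                      "(x0 = 0 and u = 0)"),
                      call = NULL)))
}

#' @export
print.sensitivity_columns <- function(x, ...) {
  cat(sprintf("Sensitivity columns q_j(s): %d parameters, %d output(s), degree bound %d\n",
              length(x$param_order), x$n_y, x$degree_bound))
  cat(sprintf("  common denominator: s^%d * Delta^2  (input mode '%s')\n",
              x$m, x$input_mode))
  if (x$cancelled != "1")
    cat("  cancelled common factor:", x$cancelled, "\n")
  for (j in seq_along(x$param_order)) {
    for (i in seq_len(x$n_y)) {
      e <- x$columns[[j]][[i]]
      tag <- if (x$n_y > 1) sprintf(" [%s]", x$outputs[i]) else ""
      cat(sprintf("  q_%s%s = %s\n", x$param_order[j], tag, lp_to_string(e)))
    }
  }
  invisible(x)
}
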