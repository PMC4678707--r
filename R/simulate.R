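# Numerical verification: exact linear-ODE simulation, least-squares
# refitting, repeated-refit correlation scans, and the finite-difference
# sensitivity rank oracle.

#' Simulate noise-free output data from a linear model
#'
#' Propagates the exact solution of \eqn{\dot x = Ax + Bu} with constant
#' controls via the matrix exponential of the augmented system
#' \eqn{[A, Bu_0; 0, 0]} between time points, and returns the noise-free
#' outputs \eqn{y = Cx + Du_0}.
#'
#' @param object a \code{linear_model}.
#' @param nsim,seed unused (noise-free data); kept for the generic.
#' @param values named numeric vector of parameter values (all parameters).
#' @param condition a fully numeric \code{experiment}.
#' @param times strictly increasing time points.
#' @param ... unused.
#' @return object of class \code{"linident_dataset"}: \code{times},
#'   \code{outputs} (\code{n_y} by \code{n_t} matrix), \code{condition}.
#' @examples
#' ex <- compartment_example(1)
#' d <- simulate(ex$model, values = ex$true_values,
#'               condition = ex$conditions$case1,
#'               times = seq(0, 10, length.out = 25))
#' d$outputs[, 1:4]
#' @export
simulate.linear_model <- function(object, nsim = 1, seed = NULL,
                                  values, condition, times, ...) {
  model <- object
  stopifnot(all(model$parameters %in% names(values)))
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  nc <- cond_numeric(model, condition)
  env <- as.list(values)
  env <- unlist(env)
  An <- sm_eval(model$A, env); Bn <- sm_eval(model$B, env)
  Cn <- sm_eval(model$C, env); Dn <- sm_eval(model$D, env)
  if (any(!is.finite(An)) || any(!is.finite(Cn)))
    stop("parameter values give non-finite model matrices", call. = FALSE)
  nx <- model$n_x
  bu <- Bn %*% nc$u0
  M <- rbind(cbind(An, bu), 0)
  z <- c(nc$x0, 1)
  nt <- length(times)
  X <- matrix(0, nx, nt)
  dts <- diff(c(0, times))
  # cache the exponential per distinct step (uniform grids need just one)
  keys <- as.character(signif(dts, 12))
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nt)) {
    if (dts[k] > 0) {
      P <- cache[[keys[k]]]
      if (is.null(P)) {
        P <- as.matrix(Matrix::expm(M * dts[k]))
        cache[[keys[k]]] <- P
      }
      z <- as.vector(P %*% z)
    }
    X[, k] <- z[seq_len(nx)]
  }
  Y <- Cn %*% X + matrix(Dn %*% nc$u0, model$n_y, nt)
  structure(list(times = times, outputs = Y, states = X,
                 condition = structure(list(x0 = as.list(nc$x0),
                                            u0 = as.list(nc$u0)),
                                       class = "experiment"),
                 outputs_names = model$outputs),
            class = "linident_dataset")
}

#' @export
print.linident_dataset <- function(x, ...) {
  cat(sprintf("Noise-free dataset: %d output(s) at %d time points on [%g, %g]\n",
              nrow(x$outputs), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Least-squares parameter fit to noise-free datasets
#'
#' Minimizes the stacked sum of squared output residuals over one or more
#' datasets with bounded Levenberg-Marquardt least squares
#' (\code{minpack.lm::nls.lm}), optionally holding some parameters fixed.
#' Multiple seeded starts guard against poor local minima; the best residual
#' is returned.
#'
#' @param model a \code{linear_model}.
#' @param datasets a dataset from \code{\link{simulate.linear_model}} or a
#'   list of them.
#' @param start named numeric starting values for the free parameters.
#' @param fixed named numeric vector of parameters held constant.
#' @param lower,upper positive-parameter box bounds.
#' @param n_starts number of seeded multi-starts (the first is
#'   \code{start} itself).
#' @param seed seed for the start jitter.
#' @param control passed to \code{minpack.lm::nls.lm.control}.
#' @return object of class \code{"linident_fit"}: \code{estimates},
#'   \code{fixed}, \code{residual_norm}, \code{converged}.
#' @examples
#' ex <- compartment_example(1)
#' d <- simulate(ex$model, values = ex$true_values,
#'               condition = ex$conditions$case1,
#'               times = seq(0, 10, length.out = 40))
#' f <- fit_parameters(ex$model, d,
#'                     start = c(p1 = 0.5, p2 = 0.5, p3 = 0.5, p4 = 0.5),
#'                     fixed = c(V = 1), n_starts = 1)
#' coef(f)
#' @export
fit_parameters <- function(model, datasets, start, fixed = NULL,
                           lower = 1e-6, upper = 1e3, n_starts = 5,
                           seed = DEFAULT_SEED,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-12, ptol = 1e-12, maxiter = 300)) {
  if (inherits(datasets, "linident_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  free <- setdiff(model$parameters, names(fixed))
  if (!all(free %in% names(start)))
    stop(sprintf("start must cover the free parameters: %s",
                 paste(setdiff(free, names(start)), collapse = ", ")),
         call. = FALSE)
  start <- start[free]
  resid_fn <- function(par) {
    values <- c(stats::setNames(par, free), fixed)
    unlist(lapply(datasets, function(d) {
      sim <- simulate.linear_model(model, values = values,
                                   condition = d$condition, times = d$times)
      as.vector(sim$outputs - d$outputs)
    }))
  }
  starts <- list(pmin(pmax(start, lower), upper))
  if (n_starts > 1) {
    jit <- with_seed(seed, function()
      lapply(seq_len(n_starts - 1), function(i)
        pmin(pmax(start * exp(stats::rnorm(length(start), 0, 0.5)),
                  lower), upper)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resid_fn,
                         lower = rep(lower, length(free)),
                         upper = rep(upper, length(free)),
                         control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    return(structure(list(estimates = stats::setNames(rep(NA_real_, length(free)), free),
                          fixed = fixed, residual_norm = NA_real_,
                          converged = FALSE),
                     class = "linident_fit"))
  structure(list(estimates = stats::setNames(as.numeric(best$fit$par), free),
                 fixed = fixed,
                 residual_norm = sqrt(best$ssr),
                 residuals = as.numeric(best$fit$fvec),
                 converged = best$fit$info %in% 1:4,
                 info = best$fit$info,
                 niter = best$fit$niter),
            class = "linident_fit")
}

#' @export
coef.linident_fit <- function(object, ...) c(object$estimates, object$fixed)

#' @export
residuals.linident_fit <- function(object, ...) object$residuals

#' @export
print.linident_fit <- function(x, ...) {
  cat("Least-squares fit",
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  est <- signif(x$estimates, 6)
  cat("  estimates:", paste(names(est), est, sep = " = ", collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:    ", paste(names(x$fixed), x$fixed, sep = " = ", collapse = ", "), "\n")
  cat("  residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Repeated-refit correlation scan
#'
#' Re-estimates the model repeatedly while one parameter is fixed at a
#' sweep of values, warm-starting each fit from the previous solution.
#' Along a correlated group the fits all reach (numerically) zero residual
#' while the estimates trace out the correlation surface, so any
#' identifiable combination stays constant across the rows.
#'
#' @param model a \code{linear_model}.
#' @param datasets dataset(s) the parameters are fitted to.
#' @param sweep_param name of the parameter to fix.
#' @param sweep_values vector of values for it.
#' @param start named numeric starting values for the remaining parameters.
#' @param fixed additional parameters held constant throughout.
#' @param ... passed to \code{\link{fit_parameters}}.
#' @return a \code{data.frame} of class \code{"correlation_scan"}: one row
#'   per sweep value with the fitted estimates, \code{residual_norm} and
#'   \code{converged}.
#' @examples
#' ex <- compartment_example(1)
#' d <- simulate(ex$model, values = ex$true_values,
#'               condition = ex$conditions$case1,
#'               times = seq(0, 10, length.out = 40))
#' sc <- correlation_scan(ex$model, d, "p1", c(0.5, 0.7, 0.9),
#'                        start = c(p2 = 0.5, p3 = 0.5, p4 = 0.5),
#'                        fixed = c(V = 1), n_starts = 1)
#' round(sc$p2 * sc$p3, 4)
#' @export
correlation_scan <- function(model, datasets, sweep_param, sweep_values,
                             start, fixed = NULL, ...) {
  stopifnot(sweep_param %in% model$parameters)
  free <- setdiff(model$parameters, c(sweep_param, names(fixed)))
  ests <- list(); resn <- numeric(0); conv <- logical(0)
  cur <- start
  for (v in sweep_values) {
    fit <- fit_parameters(model, datasets, start = cur,
                          fixed = c(stats::setNames(v, sweep_param), fixed), ...)
    est <- fit$estimates
    if (fit$converged && all(is.finite(est))) cur <- est
    ests[[length(ests) + 1]] <- est
    resn <- c(resn, fit$residual_norm)
    conv <- c(conv, isTRUE(fit$converged))
  }
  # the first rows run from a cold start; re-fit any row whose residual is
  # far above the best row, warm-started from its best-fitted neighbour
  best <- which.min(resn)
  for (i in seq_along(sweep_values)) {
    if (is.finite(resn[i]) && resn[i] <= 1e3 * max(resn[best], 1e-14)) next
    nb <- order(abs(seq_along(resn) - i))
    nb <- nb[nb != i][which.min(resn[nb[nb != i]])]
    fit <- fit_parameters(model, datasets, start = ests[[nb]],
                          fixed = c(stats::setNames(sweep_values[i], sweep_param),
                                    fixed), ...)
    if (is.finite(fit$residual_norm) && fit$residual_norm < resn[i]) {
      ests[[i]] <- fit$estimates
      resn[i] <- fit$residual_norm
      conv[i] <- isTRUE(fit$converged)
    }
  }
  rows <- lapply(seq_along(sweep_values), function(i)
    c(stats::setNames(sweep_values[i], sweep_param), ests[[i]],
      residual_norm = resn[i], converged = as.numeric(conv[i])))
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "sweep_param") <- sweep_param
  class(out) <- c("correlation_scan", "data.frame")
  out
}

#' @export
print.correlation_scan <- function(x, ...) {
  cat(sprintf("Correlation scan over '%s' (%d refits, max residual %.3g)\n",
              attr(x, "sweep_param"), nrow(x), max(x$residual_norm)))
  print.data.frame(signif(as.data.frame(x), 5), row.names = FALSE)
  invisible(x)
}

#' @export
plot.correlation_scan <- function(x, ...) {
  sp <- attr(x, "sweep_param")
  est <- setdiff(colnames(x), c(sp, "residual_norm", "converged"))
  graphics::matplot(x[[sp]], as.matrix(x[, est, drop = FALSE]), type = "b",
                    pch = seq_along(est), lty = 1,
                    xlab = sp, ylab = "fitted estimate", ...)
  graphics::legend("topright", legend = est, pch = seq_along(est),
                   col = seq_along(est), bty = "n")
  invisible(x)
}

#' Finite-difference sensitivity rank (time-domain oracle)
#'
#' Computes central-difference output sensitivities \eqn{\partial
#' y/\partial p_j} from simulation, stacks them over the time grid, and
#' returns the numeric rank of the resulting matrix.  This is an
#' independent, Laplace-free check of the symbolic correlation analysis:
#' the rank equals the number of parameters minus the nullspace dimension.
#'
#' @param model a \code{linear_model}.
#' @param values named numeric vector of parameter values.
#' @param condition a fully numeric \code{experiment}.
#' @param times time grid for the stacked sensitivities.
#' @param rel_step relative central-difference step.
#' @param tol singular values below \code{tol} times the largest are zero.
#' @return integer rank.
#' @examples
#' ex <- compartment_example(1)
#' fd_sensitivity_rank(ex$model, ex$true_values, ex$conditions$case1,
#'                     seq(0, 10, length.out = 30))
#' @export
fd_sensitivity_rank <- function(model, values, condition, times,
                                rel_step = 1e-6, tol = RANK_TOL) {
  values <- values[model$parameters]
  cols <- lapply(model$parameters, function(p) {
    h <- rel_step * max(abs(values[[p]]), 1)
    vp <- values; vp[[p]] <- vp[[p]] + h
    vm <- values; vm[[p]] <- vm[[p]] - h
    yp <- simulate.linear_model(model, values = vp, condition = condition,
                                times = times)$outputs
    ym <- simulate.linear_model(model, values = vm, condition = condition,
                                times = times)$outputs
    as.vector((yp - ym) / (2 * h))
  })
  S <- do.call(cbind, cols)
  if (all(abs(S) < 1e-14)) return(0L)
  num_rank(S, tol = tol)
}
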