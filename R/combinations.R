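# Identifiable parameter combinations.
#
# A function phi(p) of correlated parameters is identifiable precisely when
# its directional derivative along every nullspace vector alpha vanishes:
#     sum_j alpha_j dphi/dp_j == 0        (a linear first-order PDE).
# With a polynomial ansatz phi = sum_m c_m m(p) over all monomials up to a
# total degree, the PDE becomes an exact linear system in the rational
# constants c, solved over Q.  The solution space is then reduced to a
# canonical generating set: lowest degree first, then fewest terms, with
# candidates reduced modulo products of already-selected invariants and
# accepted only when they are functionally independent (numeric Jacobian
# rank) of the selection so far.

# ---- exact rational dense matrices -------------------------------------

rq_rref <- function(num, den) {
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0); piv_cols <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    pr <- which(num[row:nr, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row - 1L
    if (pr != row) {
      tmp <- num[row, ]; num[row, ] <- num[pr, ]; num[pr, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[pr, ]; den[pr, ] <- tmp
    }
    # scale pivot row to 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_mul(num[row, ], den[row, ], rep(pd, nc), rep(pn, nc))
    num[row, ] <- r$num; den[row, ] <- r$den
    for (i in seq_len(nr)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      prod <- rat_mul(rep(-fn, nc), rep(fd, nc), num[row, ], den[row, ])
      r <- rat_add(num[i, ], den[i, ], prod$num, prod$den)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, row); piv_cols <- c(piv_cols, col)
    row <- row + 1L
  }
  list(num = num, den = den, piv_rows = pivots, piv_cols = piv_cols)
}

rq_nullspace <- function(num, den) {
  rr <- rq_rref(num, den)
  nc <- ncol(num)
  free <- setdiff(seq_len(nc), rr$piv_cols)
  lapply(free, function(fc) {
    vn <- numeric(nc); vd <- rep(1, nc)
    vn[fc] <- 1
    for (k in seq_along(rr$piv_cols)) {
      vn[rr$piv_cols[k]] <- -rr$num[rr$piv_rows[k], fc]
      vd[rr$piv_cols[k]] <- rr$den[rr$piv_rows[k], fc]
    }
    list(num = vn, den = vd)
  })
}

# reduce vector v (num/den) against the pivot rows of an rref; returns residual
rq_reduce <- function(rr, vn, vd) {
  for (k in seq_along(rr$piv_cols)) {
    pc <- rr$piv_cols[k]
    if (vn[pc] == 0) next
    fn <- vn[pc]; fd <- vd[pc]    # pivot entry of rr is 1
    nc <- length(vn)
    prod <- rat_mul(rep(-fn, nc), rep(fd, nc),
                    rr$num[rr$piv_rows[k], ], rr$den[rr$piv_rows[k], ])
    r <- rat_add(vn, vd, prod$num, prod$den)
    vn <- r$num; vd <- r$den
  }
  list(num = vn, den = vd)
}

# ---- monomial bookkeeping ----------------------------------------------

# all exponent vectors over k variables with total degree in 1..maxdeg
mono_exponents <- function(k, maxdeg) {
  grow <- function(prefix, left, pos) {
    if (pos == k) return(list(c(prefix, left)))
    out <- list()
    for (e in 0:left)
      out <- c(out, grow(c(prefix, e), left - e, pos + 1))
    out
  }
  out <- list()
  for (d in seq_len(maxdeg))
    out <- c(out, grow(integer(0), d, 1))
  out
}

mono_poly <- function(vars, e) {
  lp_norm(vars, matrix(as.integer(e), 1), 1, 1)
}

# coefficient vector of a polynomial in the monomial basis (degree<=maxdeg,
# vars = support parameters); NULL if the polynomial leaves the basis
poly_to_coefvec <- function(p, vars, keys) {
  vn <- numeric(length(keys)); vd <- rep(1, length(keys))
  if (lp_is_zero(p)) return(list(num = vn, den = vd))
  if (!all(p$vars %in% vars)) return(NULL)
  expo <- matrix(0L, length(p$num), length(vars))
  expo[, match(p$vars, vars)] <- p$expo
  kk <- apply(expo, 1, paste, collapse = ",")
  idx <- match(kk, keys)
  if (anyNA(idx)) return(NULL)
  vn[idx] <- p$num; vd[idx] <- p$den
  list(num = vn, den = vd)
}

# ---- public operations -------------------------------------------------

#' Directional-derivative residuals of a candidate combination
#'
#' For each nullspace vector \eqn{\alpha} (denominators cleared), computes
#' the directional derivative \eqn{\sum_j \alpha_j \partial\phi/\partial
#' p_j} exactly.  An all-zero result certifies that \eqn{\phi} is an
#' identifiable combination.
#'
#' @param phi a combination: expression string, or a symbolic value.
#' @param basis list of nullspace vectors (from
#'   \code{\link{nullspace_basis}} or an \code{identifiability} object).
#' @param parameters parameter order matching the basis entries.
#' @return list of symbolic residuals (class \code{"lrf"}), one per basis
#'   vector; use \code{is_zero_residual()} or \code{format()} on them.
#' @examples
#' ex <- compartment_example(1)
#' rep1 <- identifiability(ex$model, ex$conditions$case1,
#'                         parameters = c("p1", "p2", "p3", "p4"))
#' invariance_residual("p2*p3", rep1$basis, rep1$parameters)
#' @export
invariance_residual <- function(phi, basis, parameters) {
  phi <- as_rf(phi)
  if (!rf_den_is_one(phi))
    stop("phi must be polynomial in the parameters", call. = FALSE)
  extra <- setdiff(phi$num$vars, parameters)
  if (length(extra))
    stop(sprintf("phi contains symbols outside the parameters: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  lapply(basis, function(v) {
    vv <- clear_vector(v)
    acc <- lp_zero()
    for (j in seq_along(parameters)) {
      if (lp_is_zero(vv[[j]])) next
      d <- lp_deriv(phi$num, parameters[j])
      if (!lp_is_zero(d)) acc <- lp_add(acc, lp_mul(vv[[j]], d))
    }
    rf_from_poly(acc)
  })
}

#' @rdname invariance_residual
#' @param residuals result of \code{invariance_residual}.
#' @export
is_zero_residual <- function(residuals) {
  all(vapply(residuals, rf_is_zero, logical(1)))
}

# clear the rational entries of a nullspace vector to polynomials
clear_vector <- function(v) {
  entries <- v$entries
  den <- lp_const(1)
  for (e in entries) {
    if (rf_is_zero(e) || rf_den_is_one(e)) next
    g <- lp_gcd(den, e$den)
    den <- lp_divexact(lp_mul(den, e$den), g)
  }
  lapply(entries, function(e) {
    if (rf_is_zero(e)) return(lp_zero())
    lp_mul(e$num, lp_divexact(den, e$den))
  })
}

#' Identifiable parameter combinations by polynomial ansatz
#'
#' Solves the invariance condition for a generic polynomial
#' \eqn{\phi = \sum_m c_m\, m(p)} over all monomials of total degree up to
#' \code{max_degree} in the correlated parameters, and reduces the solution
#' space to a canonical generating set of functionally independent
#' combinations (a group of size k bound by an r-dimensional nullspace has
#' k - r of them).
#'
#' @param basis list of nullspace vectors.
#' @param parameters parameter order matching the basis entries.
#' @param max_degree total-degree bound (1..4, default 3).
#' @param monomial_cap abort if the ansatz needs more monomials than this.
#' @param seed seed for the numeric independence checks.
#' @param nullity dimension of the underlying nullspace (defaults to the
#'   number of basis vectors; set explicitly when extra constraint vectors
#'   are passed).
#' @return list of combinations; each has \code{expression} (string),
#'   \code{poly}, \code{group}, \code{degree}.
#' @examples
#' ex <- compartment_example(1)
#' rep1 <- identifiability(ex$model, ex$conditions$case1,
#'                         parameters = c("p1", "p2", "p3", "p4"))
#' sapply(rep1$combinations, `[[`, "expression")
#' @export
find_combinations <- function(basis, parameters, max_degree = 3,
                              monomial_cap = 500, seed = DEFAULT_SEED,
                              nullity = length(basis)) {
  stopifnot(max_degree >= 1, max_degree <= 4)
  if (!length(basis)) return(list())
  supp_idx <- sort(unique(unlist(lapply(basis, function(v) v$support_idx))))
  supp <- parameters[supp_idx]
  k <- length(supp)
  expos <- mono_exponents(k, max_degree)
  if (length(expos) > monomial_cap)
    stop(structure(class = c("ident_ansatz_cap", "error", "condition"),
                   list(message = sprintf(
                     "combination ansatz needs %d monomials (cap %d): raise the cap or lower the degree",
                     length(expos), monomial_cap), call = NULL)))
  keys <- vapply(expos, paste, character(1), collapse = ",")
  monos <- lapply(expos, function(e) mono_poly(supp, e))

  # constraint rows: one per (basis vector, parameter-monomial of the
  # directional derivative); columns indexed by ansatz monomial
  rowmap <- new.env(parent = emptyenv())
  nrows <- 0L
  trip <- list()
  for (b in seq_along(basis)) {
    vv <- clear_vector(basis[[b]])
    gvars <- sort(unique(unlist(c(lapply(vv, function(p) p$vars), list(supp)))))
    for (ci in seq_along(monos)) {
      acc <- lp_zero()
      for (j in seq_along(parameters)) {
        if (lp_is_zero(vv[[j]])) next
        d <- lp_deriv(monos[[ci]], parameters[j])
        if (!lp_is_zero(d)) acc <- lp_add(acc, lp_mul(vv[[j]], d))
      }
      if (lp_is_zero(acc)) next
      expo <- matrix(0L, length(acc$num), length(gvars))
      expo[, match(acc$vars, gvars)] <- acc$expo
      for (t in seq_along(acc$num)) {
        key <- paste(b, paste(expo[t, ], collapse = ","), sep = "|")
        r <- rowmap[[key]]
        if (is.null(r)) {
          nrows <- nrows + 1L
          r <- nrows
          rowmap[[key]] <- r
        }
        trip <- c(trip, list(c(r, ci, acc$num[t], acc$den[t])))
      }
    }
  }
  if (nrows == 0L) {
    sol <- lapply(seq_along(monos), function(i) {
      vn <- numeric(length(monos)); vn[i] <- 1
      list(num = vn, den = rep(1, length(monos)))
    })
  } else {
    num <- matrix(0, nrows, length(monos)); den <- matrix(1, nrows, length(monos))
    for (t in trip) {
      r <- rat_add(num[t[1], t[2]], den[t[1], t[2]], t[3], t[4])
      num[t[1], t[2]] <- r$num; den[t[1], t[2]] <- r$den
    }
    sol <- rq_nullspace(num, den)
  }
  if (!length(sol)) return(list())

  target <- k - nullity
  sol_polys <- lapply(sol, function(v) coefvec_to_poly(v, monos))

  # numeric point for the functional-independence checks
  jvars <- sort(unique(unlist(c(list(supp),
    lapply(basis, function(v) unlist(lapply(v$entries, rf_vars)))))))
  env <- with_seed(seed + 17, function() {
    e <- stats::runif(length(jvars), 0.6, 1.9); names(e) <- jvars; e
  })

  selected <- list()
  while (length(selected) < target) {
    # span of products of the selected invariants, within the degree bound
    prods <- product_closure(selected, max_degree)
    pvecs <- Filter(Negate(is.null),
                    lapply(prods, poly_to_coefvec, vars = supp, keys = keys))
    rr <- NULL
    if (length(pvecs)) {
      pn <- do.call(rbind, lapply(pvecs, `[[`, "num"))
      pd <- do.call(rbind, lapply(pvecs, `[[`, "den"))
      rr <- rq_rref(pn, pd)
    }
    cands <- list()
    for (i in seq_along(sol)) {
      v <- sol[[i]]
      if (!is.null(rr)) {
        red <- rq_reduce(rr, v$num, v$den)
        if (all(red$num == 0)) next
        p <- coefvec_to_poly(red, monos)
      } else p <- sol_polys[[i]]
      if (lp_is_zero(p)) next
      cands <- c(cands, list(lp_primitive(p)))
    }
    if (!length(cands)) break
    ord <- order(vapply(cands, lp_total_degree, numeric(1)),
                 vapply(cands, function(p) length(p$num), numeric(1)),
                 vapply(cands, lp_to_string, character(1)))
    chosen <- NULL
    for (i in ord) {
      cand <- cands[[i]]
      if (jac_rank(c(selected, list(cand)), supp, env) == length(selected) + 1) {
        chosen <- cand; break
      }
    }
    if (is.null(chosen)) break
    selected <- c(selected, list(chosen))
  }

  lapply(selected, function(p) {
    list(expression = lp_to_string(p), poly = p,
         group = intersect(supp, p$vars),
         degree = lp_total_degree(p))
  })
}

coefvec_to_poly <- function(v, monos) {
  acc <- lp_zero()
  for (i in seq_along(monos))
    if (v$num[i] != 0)
      acc <- lp_add(acc, lp_scale(monos[[i]], v$num[i], v$den[i]))
  acc
}

# all products of the selected invariants (multisets, any multiplicity)
# whose expanded total degree stays within the bound
product_closure <- function(selected, maxdeg) {
  if (!length(selected)) return(list())
  out <- list()
  degs <- vapply(selected, lp_total_degree, numeric(1))
  rec <- function(i, cur, curdeg) {
    if (i > length(selected)) {
      if (curdeg >= 1) out[[length(out) + 1]] <<- cur
      return()
    }
    rec(i + 1, cur, curdeg)
    p <- cur; d <- curdeg
    repeat {
      d <- d + degs[i]
      if (d > maxdeg) break
      p <- if (is.null(p)) selected[[i]] else lp_mul(p, selected[[i]])
      rec(i + 1, p, d)
    }
  }
  rec(1, NULL, 0)
  out
}

jac_rank <- function(polys, vars, env) {
  J <- matrix(0, length(polys), length(vars))
  for (i in seq_along(polys))
    for (j in seq_along(vars))
      J[i, j] <- lp_eval(lp_deriv(polys[[i]], vars[j]), env)
  num_rank(J, tol = 1e-9)
}
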