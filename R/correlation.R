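# Correlation analysis: homogeneous coefficient system in alpha, its
# nullspace over the rational-function field, correlated groups, structural
# vs practical classification, and the minimal dataset count.

DEFAULT_SEED <- 20151214
RANK_TOL <- 1e-10

#' Coefficient system of the correlation equations
#'
#' Requiring \eqn{\sum_j \alpha_j q_j(s) = 0} for indeterminate \code{s}
#' forces every coefficient of every power of \code{s} (per output) to
#' vanish, giving a homogeneous linear system \eqn{\beta \alpha = 0} whose
#' entries are polynomials in the parameters and the condition symbols.
#'
#' @param cols a \code{sensitivity_columns} object.
#' @return object of class \code{"coefficient_system"}: \code{entries} is a
#'   row-major list of rows (each a list of polynomial entries),
#'   \code{row_labels} gives (output, s-power), \code{param_order} the
#'   column order, \code{symbols_present} the condition symbols that survive.
#' @export
coefficient_system <- function(cols) {
  stopifnot(inherits(cols, "sensitivity_columns"))
  np <- length(cols$param_order)
  rows <- list(); labels <- list()
  for (i in seq_len(cols$n_y)) {
    split_cols <- lapply(seq_len(np), function(j)
      lp_coef_split(cols$columns[[j]][[i]], LAPLACE_VAR))
    degs <- vapply(split_cols, length, numeric(1)) - 1
    for (k in 0:max(degs)) {
      row <- lapply(seq_len(np), function(j) {
        cs <- split_cols[[j]]
        if (k < length(cs)) cs[[k + 1]] else lp_zero()
      })
      if (all(vapply(row, lp_is_zero, logical(1)))) next
      rows <- c(rows, list(row))
      labels <- c(labels, list(c(output = i, s_power = k)))
    }
  }
  allvars <- unique(unlist(lapply(unlist(rows, recursive = FALSE),
                                  function(p) p$vars)))
  structure(list(entries = rows, row_labels = labels,
                 param_order = cols$param_order,
                 symbols_present = intersect(allvars, cols$condition_symbols),
                 condition_symbols = cols$condition_symbols,
                 n_rows = length(rows), n_cols = np),
            class = "coefficient_system")
}

#' @export
print.coefficient_system <- function(x, ...) {
  cat(sprintf("Coefficient system: %d equations in %d unknowns (alpha)\n",
              x$n_rows, x$n_cols))
  if (length(x$symbols_present))
    cat("  condition symbols present:", paste(x$symbols_present, collapse = ", "), "\n")
  for (r in seq_len(x$n_rows)) {
    terms <- character(0)
    for (j in seq_len(x$n_cols)) {
      e <- x$entries[[r]][[j]]
      if (!lp_is_zero(e))
        terms <- c(terms, sprintf("(%s)*a_%s", lp_to_string(e), x$param_order[j]))
    }
    cat(" ", paste(terms, collapse = " + "), "= 0\n")
  }
  invisible(x)
}

# numeric evaluation of the system at a random draw of every symbol
cs_numeric <- function(system, seed = DEFAULT_SEED, draws = 2) {
  vars <- unique(unlist(lapply(unlist(system$entries, recursive = FALSE),
                               function(p) p$vars)))
  with_seed(seed, function() {
    lapply(seq_len(draws), function(d) {
      env <- stats::runif(length(vars), 0.5, 2.0)
      names(env) <- vars
      M <- matrix(0, system$n_rows, system$n_cols)
      for (r in seq_len(system$n_rows))
        for (j in seq_len(system$n_cols))
          M[r, j] <- lp_eval(system$entries[[r]][[j]], env)
      M
    })
  })
}

num_rank <- function(M, tol = RANK_TOL) {
  if (nrow(M) == 0 || ncol(M) == 0) return(0L)
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv, 0) , na.rm = TRUE)
}

num_nullspace <- function(M, tol = RANK_TOL) {
  if (ncol(M) == 0) return(matrix(0, 0, 0))
  if (nrow(M) == 0) return(diag(ncol(M)))
  sv <- svd(M, nu = 0, nv = ncol(M))
  r <- sum(sv$d > tol * max(sv$d, 0))
  if (r == ncol(M)) return(matrix(0, ncol(M), 0))
  sv$v[, seq(r + 1, ncol(M)), drop = FALSE]
}

# ------------------------------------------------------------------------
# symbolic nullspace: numeric support detection first, then exact Gaussian
# elimination on the support columns with fewest-terms pivoting and
# simplification after every step

rf_size <- function(e) length(e$num$num) + length(e$den$num)

# rational scalar content of a polynomial: gcd of numerators / lcm of
# denominators, so p/content has coprime integer coefficients
lp_content_rat <- function(p) {
  g <- 0
  for (n in p$num) g <- int_gcd(g, n)
  l <- 1
  for (d in p$den) l <- l * d / int_gcd(l, d)
  c(g, l)
}

# rows of a homogeneous system can be rescaled freely; dividing by the
# rational content of the row keeps exact integers small during elimination
row_rescale <- function(row) {
  gn <- 0; gl <- 1
  for (e in row) {
    if (rf_is_zero(e)) next
    cn <- lp_content_rat(e$num)
    cd <- lp_content_rat(e$den)
    # entry scalar content = (cn1/cn2) / (cd1/cd2)
    n <- cn[1] * cd[2]; d <- cn[2] * cd[1]
    r <- rat_reduce(n, d)
    gn <- int_gcd(gn, r$num)
    gl <- gl * r$den / int_gcd(gl, r$den)
  }
  if (gn == 0 || (gn == 1 && gl == 1)) return(row)
  lapply(row, function(e) {
    if (rf_is_zero(e)) return(e)
    rf_make(lp_scale(e$num, gl, gn), e$den)
  })
}

stop_blowup <- function() {
  stop(structure(class = c("ident_symbolic_blowup", "error", "condition"),
                 list(message = "symbolic elimination exceeded its size budget",
                      call = NULL)))
}

# fraction-free Gauss-Jordan elimination (Bareiss/Montante): entries stay
# polynomial throughout; each update
#     row_i <- (piv * row_i - entry * row_piv) / previous_pivot
# is exactly divisible, which keeps every entry the size of a minor of the
# original matrix instead of growing multiplicatively.  Rational functions
# appear only in the final back-substituted basis vectors.
symbolic_nullspace <- function(entries, n_rows, n_cols, size_cap = 30000) {
  M <- lapply(seq_len(n_rows), function(r)
    lapply(entries[[r]], function(p) if (is_lrf(p)) {
      if (!rf_den_is_one(p)) stop("polynomial entries expected", call. = FALSE)
      p$num
    } else p))
  # clear rational coefficients row-wise (free scaling of homogeneous rows)
  M <- lapply(M, function(row) {
    l <- 1
    for (p in row) for (d in p$den) l <- l * d / int_gcd(l, d)
    if (l > 1 && l <= MAXINT)
      row <- lapply(row, function(p) if (lp_is_zero(p)) p else lp_scale(p, l, 1))
    row
  })
  piv_rows <- integer(0); piv_cols <- integer(0)
  used_rows <- logical(n_rows)
  prev_piv <- lp_const(1)
  repeat {
    best <- NULL
    for (i in seq_len(n_rows)) {
      if (used_rows[i]) next
      for (j in seq_len(n_cols)) {
        if (j %in% piv_cols) next
        e <- M[[i]][[j]]
        if (!lp_is_zero(e)) {
          sz <- length(e$num)
          if (is.null(best) || sz < best[1]) best <- c(sz, i, j)
        }
      }
    }
    if (is.null(best)) break
    pi <- best[2]; pj <- best[3]
    used_rows[pi] <- TRUE
    piv_rows <- c(piv_rows, pi); piv_cols <- c(piv_cols, pj)
    piv <- M[[pi]][[pj]]
    for (i in seq_len(n_rows)) {
      # Gaussian scheme: every not-yet-pivoted row is updated (rows with a
      # zero pivot-column entry are still scaled by piv/prev_piv) -- this is
      # what guarantees the exact divisibility by the previous pivot
      if (used_rows[i]) next
      fac <- M[[i]][[pj]]
      fac0 <- lp_is_zero(fac)
      newrow <- lapply(seq_len(n_cols), function(j) {
        if (j == pj) return(lp_zero())
        # abort before a multiplication whose raw product cannot stay small
        if (length(piv$num) * length(M[[i]][[j]]$num) > 2e5 ||
            length(fac$num) * length(M[[pi]][[j]]$num) > 2e5)
          stop_blowup()
        raw <- if (fac0) lp_mul(piv, M[[i]][[j]])
               else lp_sub(lp_mul(piv, M[[i]][[j]]), lp_mul(fac, M[[pi]][[j]]))
        if (lp_is_zero(raw)) return(raw)
        lp_divexact(raw, prev_piv)
      })
      if (sum(vapply(newrow, function(p) length(p$num), numeric(1))) > size_cap)
        stop_blowup()
      M[[i]] <- newrow
    }
    prev_piv <- piv
  }
  free <- setdiff(seq_len(n_cols), piv_cols)
  nk <- length(piv_cols)
  lapply(free, function(fc) {
    v <- replicate(n_cols, rf_zero(), simplify = FALSE)
    v[[fc]] <- rf_one()
    # back-substitution in reverse pivot order (row k has zeros in all
    # earlier pivot columns, so the system is triangular in that order)
    for (k in rev(seq_len(nk))) {
      acc <- rf_zero()
      row <- M[[piv_rows[k]]]
      for (j in seq_len(n_cols)) {
        if (j == piv_cols[k]) next
        if (lp_is_zero(row[[j]]) || rf_is_zero(v[[j]])) next
        acc <- rf_add(acc, rf_mul(rf_from_poly(row[[j]]), v[[j]]))
      }
      if (!rf_is_zero(acc))
        v[[piv_cols[k]]] <- rf_simplify(rf_div(rf_neg(acc), rf_from_poly(row[[piv_cols[k]]])))
    }
    v
  })
}

normalize_vec <- function(v) {
  lead <- NULL
  for (e in v) if (!rf_is_zero(e) && is.null(lead)) lead <- e
  if (is.null(lead)) return(v)
  lapply(v, function(e) if (rf_is_zero(e)) e else rf_simplify(rf_div(e, lead)))
}

#' Nullspace basis of the coefficient system
#'
#' Computes a canonical basis of the right nullspace over the field of
#' rational functions in the parameters and condition symbols.  The support
#' columns are located first by seeded numeric rank computations; exact
#' elimination then runs on those columns only.  Each vector is normalized
#' so its leading nonzero entry equals 1.  An empty list means all
#' \eqn{\alpha} are forced to zero: every parameter is identifiable from a
#' single dataset.
#'
#' @param system a \code{coefficient_system}.
#' @param seed seed for the numeric support detection.
#' @return list of nullspace vectors; each has \code{entries} (rational
#'   expressions), \code{support} (parameter names), \code{strings}.
#' @export
nullspace_basis <- function(system, seed = DEFAULT_SEED) {
  np <- system$n_cols
  Ms <- cs_numeric(system, seed, draws = 2)
  ns1 <- num_nullspace(Ms[[1]]); ns2 <- num_nullspace(Ms[[2]])
  dim_num <- max(ncol(ns1), ncol(ns2))
  if (dim_num == 0) return(list())
  supp <- sort(unique(c(
    which(apply(abs(ns1), 1, max) > 1e-7),
    which(apply(abs(ns2), 1, max) > 1e-7))))
  res <- nb_solve(system, supp, dim_num, seed)
  if (is.null(res)) {
    supp <- seq_len(np)
    res <- nb_solve(system, supp, dim_num, seed)
  }
  if (is.null(res)) return(nb_solve_numeric(system, supp, dim_num, seed))
  res
}

# exact elimination on the support columns; NULL if the dimension found
# does not match the numeric one (coincidental support restriction)
nb_solve <- function(system, supp, dim_num, seed) {
  # large condition-dependent systems are characterized numerically (the
  # two-draw rule still decides structural vs practical); the fully
  # symbolic route is reserved for systems it can finish
  sub_entries <- lapply(system$entries, function(r) r[supp])
  total <- sum(vapply(unlist(sub_entries, recursive = FALSE),
                      function(p) length(p$num), numeric(1)))
  has_syms <- length(intersect(
    unique(unlist(lapply(unlist(sub_entries, recursive = FALSE),
                         function(p) p$vars))),
    system$condition_symbols)) > 0
  if (has_syms && total > 250)
    return(nb_solve_numeric(system, supp, dim_num, seed))
  basis <- tryCatch(
    symbolic_nullspace(lapply(system$entries, function(r) r[supp]),
                       system$n_rows, length(supp)),
    ident_symbolic_blowup = function(e) NULL,
    error = function(e) {
      if (grepl("overflow", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(basis)) return(nb_solve_numeric(system, supp, dim_num, seed))
  if (length(basis) != dim_num) return(NULL)
  lapply(basis, function(v) {
    full <- replicate(system$n_cols, rf_zero(), simplify = FALSE)
    full[supp] <- v
    mk_nullvec(normalize_vec(full), system$param_order)
  })
}

# fallback for systems the exact elimination cannot finish: characterize
# the nullspace numerically.  Parameter values are held fixed while the
# condition symbols are redrawn, so comparing the two canonicalized numeric
# bases is exactly the re-randomization test for structural vs practical.
nb_solve_numeric <- function(system, supp, dim_num, seed) {
  vars <- unique(unlist(lapply(unlist(system$entries, recursive = FALSE),
                               function(p) p$vars)))
  csyms <- intersect(vars, system$condition_symbols)
  pvars <- setdiff(vars, csyms)
  env_draws <- with_seed(seed + 7, function() {
    pv <- stats::runif(length(pvars), 0.5, 2.0); names(pv) <- pvars
    lapply(1:2, function(d) {
      cv <- stats::runif(length(csyms), 0.5, 2.0); names(cv) <- csyms
      c(pv, cv)
    })
  })
  eval_mat <- function(env) {
    M <- matrix(0, system$n_rows, length(supp))
    for (r in seq_len(system$n_rows))
      for (j in seq_along(supp))
        M[r, j] <- lp_eval(system$entries[[r]][[supp[j]]], env)
    M
  }
  canon <- function(M) {
    ns <- num_nullspace(M)
    if (ncol(ns) == 0) return(list())
    # canonical reduced form: rref of the transposed numeric basis
    B <- t(ns)
    rowp <- 1
    for (col in seq_len(ncol(B))) {
      if (rowp > nrow(B)) break
      k <- which.max(abs(B[rowp:nrow(B), col])) + rowp - 1
      if (abs(B[k, col]) < 1e-8) next
      B[c(rowp, k), ] <- B[c(k, rowp), ]
      B[rowp, ] <- B[rowp, ] / B[rowp, col]
      for (i in seq_len(nrow(B))) if (i != rowp) B[i, ] <- B[i, ] - B[i, col] * B[rowp, ]
      rowp <- rowp + 1
    }
    lapply(seq_len(nrow(B)), function(i) B[i, ])
  }
  v1 <- canon(eval_mat(env_draws[[1]]))
  v2 <- canon(eval_mat(env_draws[[2]]))
  if (length(v1) != dim_num || length(v2) != dim_num)
    stop("nullspace dimension unstable across numeric draws", call. = FALSE)
  lapply(seq_len(dim_num), function(i) {
    x <- numeric(system$n_cols); x[supp] <- v1[[i]]
    xa <- numeric(system$n_cols); xa[supp] <- v2[[i]]
    x[abs(x) < 1e-9] <- 0
    nz <- which(x != 0)
    structure(list(entries = NULL,
                   numeric_values = x,
                   numeric_alt = xa,
                   support = system$param_order[nz],
                   support_idx = nz,
                   strings = sprintf("%.6g", x),
                   param_order = system$param_order,
                   numeric_only = TRUE),
              class = "nullspace_vector")
  })
}

mk_nullvec <- function(entries, param_order) {
  nz <- which(!vapply(entries, rf_is_zero, logical(1)))
  structure(list(entries = entries,
                 support = param_order[nz],
                 support_idx = nz,
                 strings = vapply(entries, rf_to_string, character(1)),
                 param_order = param_order),
            class = "nullspace_vector")
}

#' @export
print.nullspace_vector <- function(x, ...) {
  cat("alpha =")
  for (i in seq_along(x$entries))
    cat(sprintf("  %s: %s", x$param_order[i], x$strings[i]))
  cat("\n")
  invisible(x)
}

# ------------------------------------------------------------------------
# correlated groups as circuits: minimal column subsets that are linearly
# dependent.  Enumerated numerically in order of (size, lexicographic),
# accepting a circuit when its null direction is new, until the whole
# nullspace is spanned.

find_circuits <- function(Mnum, support_idx, r_target, max_support = 14) {
  if (length(support_idx) > max_support)
    return(NULL)
  circuits <- list()
  span <- matrix(0, ncol(Mnum), 0)
  for (size in seq_along(support_idx)) {
    combs <- utils::combn(support_idx, size, simplify = FALSE)
    for (S in combs) {
      if (length(circuits) &&
          any(vapply(circuits, function(cc) all(cc$set %in% S) && length(cc$set) < length(S),
                     logical(1)))) next
      sub <- Mnum[, S, drop = FALSE]
      rk <- num_rank(sub)
      if (rk < length(S)) {
        nv <- num_nullspace(sub)
        vfull <- matrix(0, ncol(Mnum), ncol(nv))
        vfull[S, ] <- nv
        newdim <- num_rank(cbind(span, vfull)) - num_rank(span)
        circuits <- c(circuits, list(list(set = S, new = newdim > 0)))
        if (newdim > 0) span <- cbind(span, vfull)
        if (num_rank(span) >= r_target) return(circuits)
      }
    }
    if (num_rank(span) >= r_target) break
  }
  circuits
}

# symbolic relation on one circuit: 1-dimensional restricted nullspace
circuit_vector <- function(system, set, seed = DEFAULT_SEED) {
  res <- nb_solve(system, set, 1L, seed)
  if (is.null(res) || length(res) != 1) return(NULL)
  res[[1]]
}

# ------------------------------------------------------------------------

#' Identifiability analysis of a linear state-space model
#'
#' The central analysis: builds the Laplace-domain output sensitivity
#' columns under the given experiment condition, extracts the homogeneous
#' coefficient system in the dependence weights \eqn{\alpha}, computes its
#' exact nullspace over the rational-function field, groups the correlated
#' parameters, classifies every group as structurally or practically
#' non-identifiable, derives identifiable parameter combinations, and
#' computes the minimal number of datasets needed to remedy a practical
#' non-identifiability.
#'
#' A correlation is \emph{structural} when the nullspace vector is free of
#' the condition symbols (the interrelationship holds whatever the nonzero
#' initial values and controls are), and \emph{practical} when it depends on
#' them, so that datasets from sufficiently different conditions break it.
#'
#' @param model a \code{linear_model}.
#' @param condition an \code{experiment}; nonzero entries are genericized to
#'   free symbols for the analysis.
#' @param parameters the parameters under estimation (default all model
#'   parameters); the remainder are treated as known.
#' @param input_mode \code{"generic"} (default: constant controls as free
#'   symbols, the convention under which correlation results are usually
#'   stated) or \code{"step"} (literal \eqn{u_0/s} transform).
#' @param combinations derive identifiable parameter combinations
#'   (polynomial ansatz up to \code{max_degree}).
#' @param max_degree total-degree bound of the combination ansatz (1..4).
#' @param seed seed for the deterministic numeric rank draws.
#' @return object of class \code{"identifiability"}; see Details.  Key
#'   fields: \code{status} (named vector:
#'   \code{identifiable} / \code{structurally-nonidentifiable} /
#'   \code{practically-nonidentifiable}), \code{groups} (list of parameter
#'   sets), \code{basis} (nullspace vectors), \code{combinations},
#'   \code{n_max}, \code{equations_per_dataset}, \code{n_d}.
#' @examples
#' ex <- compartment_example(1)
#' identifiability(ex$model, ex$conditions$case1,
#'                 parameters = c("p1", "p2", "p3", "p4"))
#' @export
identifiability <- function(model, condition,
                            parameters = model$parameters,
                            input_mode = c("generic", "step"),
                            combinations = TRUE, max_degree = 3,
                            seed = DEFAULT_SEED) {
  input_mode <- match.arg(input_mode)
  cols <- sensitivity_columns(model, condition, parameters = parameters,
                              input_mode = input_mode)
  system <- coefficient_system(cols)
  basis <- nullspace_basis(system, seed = seed)
  np <- length(parameters)

  Mnum <- cs_numeric(system, seed, draws = 1)[[1]]
  rank_obs <- num_rank(Mnum)

  groups <- list(); group_vectors <- list()
  if (length(basis)) {
    supp_all <- sort(unique(unlist(lapply(basis, function(v) v$support_idx))))
    circs <- find_circuits(Mnum, supp_all, r_target = length(basis))
    if (!is.null(circs)) {
      for (cc in circs) {
        if (!cc$new) next
        gv <- circuit_vector(system, cc$set)
        if (is.null(gv)) next
        groups <- c(groups, list(parameters[cc$set]))
        group_vectors <- c(group_vectors, list(gv))
      }
    }
    if (length(groups) == 0) {
      groups <- lapply(basis, function(v) v$support)
      group_vectors <- basis
    }
  }

  # classification per group
  cond_syms <- system$condition_symbols
  cls <- vapply(group_vectors, function(v)
    classify_vector(v, parameters, cond_syms, seed), character(1))

  status <- stats::setNames(rep("identifiable", np), parameters)
  for (g in seq_along(groups)) {
    lab <- if (cls[g] == "structural") "structurally-nonidentifiable"
           else "practically-nonidentifiable"
    for (p in groups[[g]])
      if (status[p] == "identifiable" || lab == "practically-nonidentifiable")
        status[p] <- lab
  }

  n_max <- if (length(groups)) max(lengths(groups)) else 0L
  eqs <- equations_per_dataset(model, cols, groups)
  n_d <- if (any(cls == "practical"))
    as.integer(ceiling(n_max / eqs)) else 0L

  combos <- list()
  all_symbolic <- !any(vapply(basis, function(v) isTRUE(v$numeric_only), logical(1)))
  if (combinations && length(basis) && all_symbolic) {
    combos <- tryCatch(
      find_combinations(basis, parameters, max_degree = max_degree, seed = seed),
      ident_ansatz_cap = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        list()
      })
  }

  structure(list(model_name = model$name,
                 parameters = parameters,
                 status = status,
                 groups = groups,
                 group_class = cls,
                 basis = basis,
                 group_vectors = group_vectors,
                 combinations = combos,
                 n_max = n_max,
                 equations_per_dataset = eqs,
                 independent_rows = rank_obs,
                 n_d = n_d,
                 input_mode = input_mode,
                 condition = cols$condition,
                 condition_symbols = cond_syms,
                 degree_bound = cols$degree_bound,
                 cancelled_factor = cols$cancelled,
                 system = system,
                 sensitivity = cols,
                 seed = seed),
            class = "identifiability")
}

classify_vector <- function(v, parameters, cond_syms, seed) {
  if (isTRUE(v$numeric_only)) {
    d <- max(abs(v$numeric_values - v$numeric_alt))
    return(if (d <= 1e-8 * max(1, max(abs(v$numeric_values)))) "structural" else "practical")
  }
  vars <- unique(unlist(lapply(v$entries, rf_vars)))
  if (!length(intersect(vars, cond_syms))) return("structural")
  # re-randomize the condition symbols twice at fixed parameter values: a
  # vector that does not move is structural despite unsimplified symbols
  pv <- with_seed(seed + 1, function() stats::runif(length(parameters), 0.5, 2.0))
  names(pv) <- parameters
  extra <- setdiff(vars, c(parameters, cond_syms))
  ev <- with_seed(seed + 2, function() stats::runif(length(extra), 0.5, 2.0))
  names(ev) <- extra
  vals <- with_seed(seed + 3, function()
    lapply(1:2, function(d) {
      cv <- stats::runif(length(cond_syms), 0.5, 2.0)
      names(cv) <- cond_syms
      c(pv, ev, cv)
    }))
  v1 <- vapply(v$entries, rf_eval, numeric(1), env = vals[[1]])
  v2 <- vapply(v$entries, rf_eval, numeric(1), env = vals[[2]])
  if (max(abs(v1 - v2)) <= 1e-10 * max(1, max(abs(v1)))) "structural" else "practical"
}

# the printed bookkeeping convention: n_y(2 n_x - 2) when every correlated
# parameter sits in A, n_y(2 n_x + 1) when all four blocks carry
# parameters, n_y(degree_bound + 1) otherwise
equations_per_dataset <- function(model, cols, groups) {
  ny <- model$n_y; nx <- model$n_x
  gp <- unique(unlist(groups))
  blocks <- model$param_blocks
  all_four <- all(vapply(blocks, length, numeric(1)) > 0)
  if (length(gp) == 0) gp <- unlist(blocks)
  if (all(gp %in% blocks$A)) return(as.integer(ny * (2 * nx - 2)))
  if (all_four) return(as.integer(ny * (2 * nx + 1)))
  as.integer(ny * (cols$degree_bound + 1))
}

#' Minimal number of datasets to remedy practical non-identifiability
#'
#' The largest correlated group of size \code{n_max} contributes
#' \code{equations_per_dataset} homogeneous equations per (noise-free)
#' dataset, so \code{ceiling(n_max / equations_per_dataset)} datasets from
#' suitably different conditions make the stacked columns independent.
#' Returns 0 when no practical correlation remains to remedy.
#'
#' @param report an \code{identifiability} object.
#' @return integer dataset count.
#' @export
required_datasets <- function(report) {
  stopifnot(inherits(report, "identifiability"))
  report$n_d
}

#' Numeric rank of stacked sensitivity columns over several conditions
#'
#' Evaluates the group's sensitivity columns at random numeric parameter
#' values and Laplace points, one block per experiment condition (each
#' condition's nonzero pattern is honoured with random values), and returns
#' the numeric rank of the stacked matrix.  Full rank certifies that the
#' conditions jointly resolve the group.
#'
#' @param model a \code{linear_model}.
#' @param conditions list of \code{experiment} objects.
#' @param group character vector of parameter names.
#' @param seed seed for all draws.
#' @param n_s number of Laplace evaluation points (default covers the
#'   polynomial degree bound).
#' @return list with \code{rank} and \code{full}.
#' @export
stacked_rank_check <- function(model, conditions, group,
                               seed = DEFAULT_SEED, n_s = NULL) {
  stopifnot(length(conditions) >= 1, length(group) >= 1,
            all(group %in% model$parameters))
  if (is.null(n_s)) n_s <- 2 * model$n_x + 3
  blocks <- with_seed(seed, function() {
    pv <- stats::runif(length(model$parameters), 0.5, 2.0)
    names(pv) <- model$parameters
    lapply(conditions, function(cond) {
      cond <- validate_condition(model, cond)
      x0 <- vapply(cond$x0, function(e)
        if (is.numeric(e) && e == 0) 0 else stats::runif(1, 0.5, 2.0), numeric(1))
      u0 <- vapply(cond$u0, function(e)
        if (is.numeric(e) && e == 0) 0 else stats::runif(1, 0.5, 2.0), numeric(1))
      sv <- stats::runif(n_s, 0.3, 3.0)
      numeric_sensitivity_block(model, pv, x0, u0, sv, group)
    })
  })
  M <- do.call(rbind, blocks)
  r <- num_rank(M)
  list(rank = r, full = r == length(group))
}

# rows = outputs x s-points, cols = group parameters; generic-input
# convention (constant controls as numeric values)
numeric_sensitivity_block <- function(model, pv, x0, u0, sv, group) {
  envA <- pv
  An <- sm_eval(model$A, envA); Bn <- sm_eval(model$B, envA)
  Cn <- sm_eval(model$C, envA); Dn <- sm_eval(model$D, envA)
  nx <- model$n_x
  dmats <- lapply(group, function(p) {
    list(dA = sm_eval(sm_apply(model$A, function(e) rf_deriv(e, p)), envA),
         dB = sm_eval(sm_apply(model$B, function(e) rf_deriv(e, p)), envA),
         dC = sm_eval(sm_apply(model$C, function(e) rf_deriv(e, p)), envA),
         dD = sm_eval(sm_apply(model$D, function(e) rf_deriv(e, p)), envA))
  })
  out <- matrix(0, 0, length(group))
  for (s in sv) {
    Minv <- solve(s * diag(nx) - An)
    X <- Minv %*% (Bn %*% u0 + x0)
    row <- vapply(seq_along(group), function(j) {
      d <- dmats[[j]]
      as.vector(Cn %*% Minv %*% (d$dA %*% X) + Cn %*% Minv %*% (d$dB %*% u0) +
                d$dC %*% X + d$dD %*% u0)
    }, numeric(model$n_y))
    out <- rbind(out, matrix(row, model$n_y, length(group)))
  }
  out
}

#' Per-output correlation relations
#'
#' For multi-output models, the correlations visible in each single output
#' taken alone refine the joint picture: each output row contributes its own
#' minimal correlated sets (circuits) and relation vectors.  Groups of size
#' one correspond to parameters the output does not excite at all.
#'
#' @param model a \code{linear_model}.
#' @param condition an \code{experiment}.
#' @param parameters parameters under estimation.
#' @param input_mode see \code{\link{identifiability}}.
#' @param min_size drop circuits smaller than this (default 2 keeps genuine
#'   relations only).
#' @param seed deterministic draw seed.
#' @return list, one entry per output, each a list of relations with
#'   \code{group} and \code{vector}.
#' @export
output_correlations <- function(model, condition,
                                parameters = model$parameters,
                                input_mode = c("generic", "step"),
                                min_size = 2, seed = DEFAULT_SEED) {
  input_mode <- match.arg(input_mode)
  out <- vector("list", model$n_y)
  names(out) <- model$outputs
  for (i in seq_len(model$n_y)) {
    sub <- restrict_outputs(model, i)
    rel <- tryCatch({
      cols <- sensitivity_columns(sub, condition, parameters = parameters,
                                  input_mode = input_mode)
      system <- coefficient_system(cols)
      basis <- nullspace_basis(system, seed = seed)
      if (!length(basis)) list()
      else {
        Mnum <- cs_numeric(system, seed, draws = 1)[[1]]
        supp <- sort(unique(unlist(lapply(basis, function(v) v$support_idx))))
        circs <- find_circuits(Mnum, supp, r_target = length(basis))
        res <- list()
        for (cc in circs %||% list()) {
          if (length(cc$set) < min_size) next
          gv <- circuit_vector(system, cc$set)
          if (!is.null(gv))
            res <- c(res, list(list(group = parameters[cc$set], vector = gv)))
        }
        res
      }
    }, ident_no_excitation = function(e) list())
    out[[i]] <- rel
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

restrict_outputs <- function(model, rows) {
  linear_model(A = model$A_chr, B = model$B_chr,
               C = model$C_chr[rows, , drop = FALSE],
               D = model$D_chr[rows, , drop = FALSE],
               states = model$states, inputs = model$inputs,
               outputs = model$outputs[rows],
               parameters = model$parameters,
               name = paste0(model$name, "[", paste(model$outputs[rows], collapse = ","), "]"))
}
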