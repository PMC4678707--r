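# Rational functions: pairs of lpoly numerator/denominator kept in lowest
# terms (gcd-reduced, denominator primitive with positive leading
# coefficient).  Polynomial values pass through with denominator 1, which
# keeps the common fast path purely polynomial.

rf_make <- function(num, den) structure(list(num = num, den = den), class = "lrf")

rf_from_poly <- function(p) rf_make(p, lp_const(1))

rf_zero <- function() rf_from_poly(lp_zero())
rf_one  <- function() rf_from_poly(lp_const(1))

is_lrf <- function(x) inherits(x, "lrf")

as_rf <- function(x) {
  if (is_lrf(x)) return(x)
  if (is_lpoly(x)) return(rf_from_poly(x))
  if (is.numeric(x) && length(x) == 1) {
    r <- dec_to_rat(format(x, scientific = FALSE, trim = TRUE, digits = 15))
    return(rf_from_poly(lp_const(r$num, r$den)))
  }
  if (is.character(x) && length(x) == 1) return(parse_expression(x))
  stop("cannot convert to rational function", call. = FALSE)
}

rf_is_zero <- function(a) lp_is_zero(a$num)

rf_den_is_one <- function(a) lp_is_const(a$den) && a$den$num == 1 && a$den$den == 1

rf_simplify <- function(a) {
  if (lp_is_zero(a$num)) return(rf_zero())
  if (lp_is_const(a$den)) {
    num <- lp_scale(a$num, a$den$den, a$den$num)
    return(rf_make(num, lp_const(1)))
  }
  g <- lp_gcd(a$num, a$den)
  if (!lp_is_const(g)) {
    a <- rf_make(lp_divexact(a$num, g), lp_divexact(a$den, g))
    if (lp_is_const(a$den)) return(rf_simplify(a))
  }
  # normalize: primitive denominator with positive leading coefficient,
  # scaling folded into the numerator
  dp <- lp_primitive(a$den)
  # a$den = c * dp  for a rational constant c; recover c from leading terms
  c_num <- a$den$num[1] * dp$den[1]
  c_den <- a$den$den[1] * dp$num[1]
  rf_make(lp_scale(a$num, c_den, c_num), dp)
}

rf_add <- function(a, b) {
  if (rf_is_zero(a)) return(b)
  if (rf_is_zero(b)) return(a)
  if (rf_den_is_one(a) && rf_den_is_one(b))
    return(rf_make(lp_add(a$num, b$num), lp_const(1)))
  rf_simplify(rf_make(
    lp_add(lp_mul(a$num, b$den), lp_mul(b$num, a$den)),
    lp_mul(a$den, b$den)))
}

rf_neg <- function(a) rf_make(lp_neg(a$num), a$den)

rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_mul <- function(a, b) {
  if (rf_is_zero(a) || rf_is_zero(b)) return(rf_zero())
  if (rf_den_is_one(a) && rf_den_is_one(b))
    return(rf_make(lp_mul(a$num, b$num), lp_const(1)))
  rf_simplify(rf_make(lp_mul(a$num, b$num), lp_mul(a$den, b$den)))
}

rf_div <- function(a, b) {
  if (rf_is_zero(b)) stop("division by zero rational function", call. = FALSE)
  if (rf_is_zero(a)) return(rf_zero())
  rf_simplify(rf_make(lp_mul(a$num, b$den), lp_mul(a$den, b$num)))
}

rf_pow <- function(a, k) {
  out <- rf_one()
  for (i in seq_len(k)) out <- rf_mul(out, a)
  out
}

rf_eval <- function(a, env) lp_eval(a$num, env) / lp_eval(a$den, env)

rf_vars <- function(a) union(a$num$vars, a$den$vars)

rf_equal <- function(a, b) {
  lp_is_zero(lp_sub(lp_mul(a$num, b$den), lp_mul(b$num, a$den)))
}

rf_to_string <- function(a) {
  if (rf_is_zero(a)) return("0")
  ns <- lp_to_string(a$num)
  if (rf_den_is_one(a)) return(ns)
  ds <- lp_to_string(a$den)
  if (length(a$num$num) > 1) ns <- paste0("(", ns, ")")
  if (length(a$den$num) > 1) ds <- paste0("(", ds, ")")
  paste0(ns, "/", ds)
}

#' @export
print.lrf <- function(x, ...) {
  cat(rf_to_string(x), "\n")
  invisible(x)
}

# ------------------------------------------------------------------------
# matrices of rational functions: plain lists with a dim attribute

sm_matrix <- function(entries, nrow, ncol) {
  stopifnot(length(entries) == nrow * ncol)
  structure(entries, dim = c(nrow, ncol), class = "lrfmat")
}

sm_get <- function(m, i, j) m[[i + (j - 1) * dim(m)[1]]]
sm_set <- function(m, i, j, v) { m[[i + (j - 1) * dim(m)[1]]] <- v; m }

sm_from_char <- function(chr) {
  # chr: character matrix of expressions
  ents <- lapply(as.vector(chr), function(e) {
    if (is.na(e) || e == "" ) rf_zero() else as_rf(e)
  })
  sm_matrix(ents, nrow(chr), ncol(chr))
}

sm_dim <- function(m) dim(m)

sm_mul <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[2] == db[1])
  out <- vector("list", da[1] * db[2])
  for (j in seq_len(db[2])) for (i in seq_len(da[1])) {
    acc <- rf_zero()
    for (k in seq_len(da[2])) {
      x <- sm_get(a, i, k); y <- sm_get(b, k, j)
      if (!rf_is_zero(x) && !rf_is_zero(y)) acc <- rf_add(acc, rf_mul(x, y))
    }
    out[[i + (j - 1) * da[1]]] <- acc
  }
  sm_matrix(out, da[1], db[2])
}

sm_add <- function(a, b) {
  da <- dim(a)
  out <- mapply(rf_add, a, b, SIMPLIFY = FALSE)
  sm_matrix(out, da[1], da[2])
}

sm_minor <- function(m, drop_i, drop_j) {
  d <- dim(m)
  keep_i <- setdiff(seq_len(d[1]), drop_i)
  keep_j <- setdiff(seq_len(d[2]), drop_j)
  ents <- vector("list", length(keep_i) * length(keep_j))
  k <- 0
  for (j in keep_j) for (i in keep_i) {
    k <- k + 1
    ents[[k]] <- sm_get(m, i, j)
  }
  sm_matrix(ents, length(keep_i), length(keep_j))
}

# determinant by cofactor expansion along the sparsest column
sm_det <- function(m) {
  d <- dim(m)
  stopifnot(d[1] == d[2])
  n <- d[1]
  if (n == 0) return(rf_one())    # empty minor (adjugate of a 1x1 matrix)
  if (n == 1) return(sm_get(m, 1, 1))
  nz <- vapply(seq_len(n), function(j)
    sum(vapply(seq_len(n), function(i) !rf_is_zero(sm_get(m, i, j)), logical(1))),
    numeric(1))
  j <- which.min(nz)
  acc <- rf_zero()
  for (i in seq_len(n)) {
    e <- sm_get(m, i, j)
    if (rf_is_zero(e)) next
    sub <- sm_det(sm_minor(m, i, j))
    term <- rf_mul(e, sub)
    if ((i + j) %% 2 == 1) term <- rf_neg(term)
    acc <- rf_add(acc, term)
  }
  acc
}

# adjugate: adj(M)[j,i] = (-1)^(i+j) det(M minor i,j)
sm_adjugate <- function(m) {
  n <- dim(m)[1]
  out <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cf <- sm_det(sm_minor(m, i, j))
    if ((i + j) %% 2 == 1) cf <- rf_neg(cf)
    out[[j + (i - 1) * n]] <- cf     # transposed position
  }
  sm_matrix(out, n, n)
}

sm_apply <- function(m, f) {
  d <- dim(m)
  sm_matrix(lapply(m, f), d[1], d[2])
}

sm_eval <- function(m, env) {
  d <- dim(m)
  matrix(vapply(m, rf_eval, numeric(1), env = env), d[1], d[2])
}
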