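# Exact sparse multivariate polynomial arithmetic over the rationals.
#
# A polynomial is stored as a term list: an integer exponent matrix (one row
# per term, one column per variable) plus exact rational coefficients kept as
# numerator/denominator pairs in doubles (exact up to 2^53; overflow aborts
# rather than silently losing precision).  Canonical form -- variables sorted,
# terms in descending graded-lexicographic order, no zero or duplicate terms,
# unused variables dropped -- makes equality and zero tests structural.

MAXINT <- 2^52

int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  # inputs beyond 2^52 may already be rounded doubles; refuse before the
  # gcd turns silent rounding into wrong exact arithmetic
  if (any(abs(num) > MAXINT) || any(abs(den) > MAXINT))
    stop("rational coefficient overflow in exact arithmetic", call. = FALSE)
  neg <- den < 0
  num[neg] <- -num[neg]; den[neg] <- -den[neg]
  g <- mapply(int_gcd, num, den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  if (any(abs(num) > MAXINT) || any(den > MAXINT))
    stop("rational coefficient overflow in exact arithmetic", call. = FALSE)
  list(num = num, den = den)
}

# a/b + c/d elementwise
rat_add <- function(an, ad, bn, bd) rat_reduce(an * bd + bn * ad, ad * bd)
rat_mul <- function(an, ad, bn, bd) rat_reduce(an * bn, ad * bd)

lp_make <- function(vars, expo, num, den) {
  structure(list(vars = vars, expo = expo, num = num, den = den),
            class = "lpoly")
}

lp_zero <- function() lp_make(character(0), matrix(0L, 0, 0), numeric(0), numeric(0))

lp_const <- function(num, den = 1) {
  r <- rat_reduce(num, den)
  if (r$num == 0) return(lp_zero())
  lp_make(character(0), matrix(0L, 1, 0), r$num, r$den)
}

lp_var <- function(name, pow = 1L) {
  lp_make(name, matrix(as.integer(pow), 1, 1), 1, 1)
}

is_lpoly <- function(x) inherits(x, "lpoly")

lp_is_zero <- function(p) length(p$num) == 0

lp_is_const <- function(p) length(p$vars) == 0

# canonical graded-lex descending order of the rows of an exponent matrix
lp_term_order <- function(expo) {
  if (nrow(expo) <= 1) return(seq_len(nrow(expo)))
  tot <- rowSums(expo)
  cols <- lapply(seq_len(ncol(expo)), function(j) -expo[, j])
  do.call(order, c(list(-tot), cols))
}

# normalize a raw term list into canonical form (merges duplicates)
lp_norm <- function(vars, expo, num, den) {
  if (length(vars) > 1 && is.unsorted(vars)) {
    ord <- order(vars)
    vars <- vars[ord]
    expo <- expo[, ord, drop = FALSE]
  }
  keep <- num != 0
  expo <- expo[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
  if (length(num) == 0) return(lp_zero())
  if (length(vars) == 0 || all(colSums(expo) == 0)) {
    nn <- num[1]; dd <- den[1]
    for (i in seq_along(num)[-1]) {
      r <- rat_add(nn, dd, num[i], den[i])
      nn <- r$num; dd <- r$den
    }
    if (nn == 0) return(lp_zero())
    return(lp_make(character(0), matrix(0L, 1, 0), nn, dd))
  }
  if (length(vars) > 0) {
    key <- do.call(paste, c(as.data.frame(expo), sep = ","))
    if (anyDuplicated(key)) {
      groups <- split(seq_along(key), key)
      idx <- vapply(groups, `[`, integer(1), 1)
      n2 <- numeric(length(groups)); d2 <- numeric(length(groups))
      k <- 0
      for (g in groups) {
        k <- k + 1
        nn <- num[g[1]]; dd <- den[g[1]]
        for (i in g[-1]) {
          r <- rat_add(nn, dd, num[i], den[i])
          nn <- r$num; dd <- r$den
        }
        n2[k] <- nn; d2[k] <- dd
      }
      expo <- expo[idx, , drop = FALSE]; num <- n2; den <- d2
      keep <- num != 0
      expo <- expo[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
      if (length(num) == 0) return(lp_zero())
    }
    used <- colSums(expo) > 0
    vars <- vars[used]; expo <- expo[, used, drop = FALSE]
  }
  ord <- lp_term_order(expo)
  lp_make(vars, expo[ord, , drop = FALSE], num[ord], den[ord])
}

# align two polynomials onto the union of their variables
lp_align <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  ea <- matrix(0L, nrow(a$expo), length(vars), dimnames = NULL)
  eb <- matrix(0L, nrow(b$expo), length(vars))
  if (length(a$vars)) ea[, match(a$vars, vars)] <- a$expo
  if (length(b$vars)) eb[, match(b$vars, vars)] <- b$expo
  list(vars = vars, ea = ea, eb = eb)
}

lp_add <- function(a, b) {
  if (lp_is_zero(a)) return(b)
  if (lp_is_zero(b)) return(a)
  al <- lp_align(a, b)
  lp_norm(al$vars, rbind(al$ea, al$eb), c(a$num, b$num), c(a$den, b$den))
}

lp_neg <- function(a) { a$num <- -a$num; a }

lp_sub <- function(a, b) lp_add(a, lp_neg(b))

lp_scale <- function(a, num, den = 1) {
  if (num == 0 || lp_is_zero(a)) return(lp_zero())
  r <- rat_mul(a$num, a$den, rep(num, length(a$num)), rep(den, length(a$num)))
  lp_make(a$vars, a$expo, r$num, r$den)
}

lp_mul <- function(a, b) {
  if (lp_is_zero(a) || lp_is_zero(b)) return(lp_zero())
  if (lp_is_const(a)) return(lp_scale(b, a$num, a$den))
  if (lp_is_const(b)) return(lp_scale(a, b$num, b$den))
  al <- lp_align(a, b)
  na <- nrow(al$ea); nb <- nrow(al$eb)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  expo <- al$ea[ia, , drop = FALSE] + al$eb[ib, , drop = FALSE]
  r <- rat_mul(a$num[ia], a$den[ia], b$num[ib], b$den[ib])
  lp_norm(al$vars, expo, r$num, r$den)
}

lp_pow <- function(a, k) {
  k <- as.integer(k)
  stopifnot(k >= 0)
  out <- lp_const(1)
  base <- a
  while (k > 0) {
    if (k %% 2L == 1L) out <- lp_mul(out, base)
    k <- k %/% 2L
    if (k > 0) base <- lp_mul(base, base)
  }
  out
}

lp_deriv <- function(a, v) {
  j <- match(v, a$vars)
  if (is.na(j)) return(lp_zero())
  e <- a$expo[, j]
  keep <- e > 0
  if (!any(keep)) return(lp_zero())
  expo <- a$expo[keep, , drop = FALSE]
  num <- a$num[keep] * e[keep]
  expo[, j] <- expo[, j] - 1L
  lp_norm(a$vars, expo, num, a$den[keep])
}

lp_total_degree <- function(a) {
  if (lp_is_zero(a)) return(-Inf)
  if (length(a$vars) == 0) return(0L)
  max(rowSums(a$expo))
}

lp_degree <- function(a, v) {
  j <- match(v, a$vars)
  if (is.na(j) || lp_is_zero(a)) return(0L)
  max(a$expo[, j])
}

# substitute 0 for the given variables (drop every term containing them)
lp_subs_zero <- function(a, vars0) {
  j <- which(a$vars %in% vars0)
  if (length(j) == 0 || lp_is_zero(a)) return(a)
  keep <- rowSums(a$expo[, j, drop = FALSE]) == 0
  lp_norm(a$vars, a$expo[keep, , drop = FALSE], a$num[keep], a$den[keep])
}

# exact substitution of small integers for selected variables
lp_subs_int <- function(a, vals) {
  j <- which(a$vars %in% names(vals))
  if (length(j) == 0 || lp_is_zero(a)) return(a)
  num <- a$num
  for (jj in j) {
    v <- vals[[a$vars[jj]]]
    num <- num * v^a$expo[, jj]
  }
  if (any(abs(num) > MAXINT))
    stop("rational coefficient overflow in exact arithmetic", call. = FALSE)
  lp_norm(a$vars[-j], a$expo[, -j, drop = FALSE], num, a$den)
}

# numeric evaluation; env is a named numeric vector covering all variables
lp_eval <- function(a, env) {
  if (lp_is_zero(a)) return(0)
  val <- a$num / a$den
  for (j in seq_along(a$vars)) {
    val <- val * env[[a$vars[j]]]^a$expo[, j]
  }
  sum(val)
}

# split into coefficient polynomials of powers of variable v:
# returns list with entries for powers 0..deg (some possibly zero polys)
lp_coef_split <- function(a, v) {
  j <- match(v, a$vars)
  if (is.na(j)) return(list(a))
  d <- max(a$expo[, j])
  out <- vector("list", d + 1)
  for (k in 0:d) {
    keep <- a$expo[, j] == k
    out[[k + 1]] <- lp_norm(a$vars[-j], a$expo[keep, -j, drop = FALSE],
                            a$num[keep], a$den[keep])
  }
  out
}

# leading term (canonical order) utilities -------------------------------

lp_lead <- function(a) list(expo = a$expo[1, ], num = a$num[1], den = a$den[1])

# does monomial e2 divide e1 (componentwise), vectors on same vars?
expo_divides <- function(e2, e1) all(e1 >= e2)

# multivariate division: returns list(q = quotient, r = remainder) such that
# a = q*b + r and no term of r is divisible by the leading term of b.
# The leading term of a sub-variable polynomial is also leading on any
# variable superset (omitted exponents are uniformly zero), so the canonical
# per-polynomial ordering can be reused without re-alignment.
lp_divmod <- function(a, b) {
  stopifnot(!lp_is_zero(b))
  vars <- sort(union(a$vars, b$vars))
  lbe <- integer(length(vars)); names(lbe) <- vars
  if (length(b$vars)) lbe[b$vars] <- b$expo[1, ]
  lbn <- b$num[1]; lbd <- b$den[1]
  q <- lp_zero(); r <- lp_zero()
  f <- a
  guard <- 0L
  while (!lp_is_zero(f)) {
    guard <- guard + 1L
    if (guard > 200000L) stop("division did not terminate", call. = FALSE)
    lfe <- integer(length(vars)); names(lfe) <- vars
    if (length(f$vars)) {
      known <- intersect(f$vars, vars)
      lfe[known] <- f$expo[1, match(known, f$vars)]
    }
    if (all(lfe >= lbe)) {
      co <- rat_reduce(f$num[1] * lbd, f$den[1] * lbn)
      t <- lp_norm(vars, matrix(lfe - lbe, 1), co$num, co$den)
      q <- lp_add(q, t)
      f <- lp_sub(f, lp_mul(t, b))
    } else {
      lead <- lp_make(f$vars, f$expo[1, , drop = FALSE], f$num[1], f$den[1])
      r <- lp_add(r, lead)
      f <- lp_norm(f$vars, f$expo[-1, , drop = FALSE], f$num[-1], f$den[-1])
    }
  }
  list(q = q, r = r)
}

# exact division (stops if not exact)
lp_divexact <- function(a, b) {
  if (lp_is_const(b)) return(lp_scale(a, b$den, b$num))
  d <- lp_divmod(a, b)
  if (!lp_is_zero(d$r)) stop("inexact polynomial division", call. = FALSE)
  d$q
}

# integer-primitive normalization: scale so coefficients are integers with
# gcd 1 and the leading (canonical order) coefficient is positive
lp_primitive <- function(a) {
  if (lp_is_zero(a)) return(a)
  denlcm <- 1
  for (d in a$den) {
    denlcm <- denlcm * d / int_gcd(denlcm, d)
    if (denlcm > MAXINT)
      stop("rational coefficient overflow in exact arithmetic", call. = FALSE)
  }
  num <- a$num * (denlcm / a$den)
  if (any(abs(num) > MAXINT))
    stop("rational coefficient overflow in exact arithmetic", call. = FALSE)
  g <- 0
  for (n in num) g <- int_gcd(g, n)
  if (g == 0) g <- 1
  num <- num / g
  if (num[1] < 0) num <- -num
  lp_make(a$vars, a$expo, num, rep(1, length(num)))
}

# monomial content: per-variable minimum exponent across all terms
lp_mono_content <- function(a) {
  if (lp_is_zero(a) || length(a$vars) == 0)
    return(lp_const(1))
  mins <- apply(a$expo, 2, min)
  if (all(mins == 0)) return(lp_const(1))
  lp_make(a$vars[mins > 0], matrix(mins[mins > 0], 1), 1, 1)
}

lp_strip_mono <- function(a, mono) {
  if (lp_is_const(mono)) return(a)
  expo <- a$expo
  j <- match(mono$vars, a$vars)
  expo[, j] <- sweep(expo[, j, drop = FALSE], 2, as.integer(mono$expo[1, ]), "-")
  lp_norm(a$vars, expo, a$num, a$den)
}

# ------------------------------------------------------------------------
# multivariate gcd via primitive-PRS Euclid with monomial-content stripping.
# A step budget guards against pathological blowup: on exhaustion the gcd
# degenerates to the monomial content, which is always a valid divisor.

lp_gcd <- function(a, b, budget = 30000L) {
  # very large inputs: settle for the (always valid) monomial-content gcd
  if (length(a$num) + length(b$num) > 2000L)
    return(mono_gcd(lp_mono_content(a), lp_mono_content(b)))
  env <- new.env(); env$steps <- 0L
  res <- tryCatch(lp_gcd_rec(lp_primitive(a), lp_primitive(b), env, budget),
                  lpoly_budget = function(e) NULL,
                  error = function(e) {
                    if (grepl("overflow", conditionMessage(e))) NULL else stop(e)
                  })
  if (is.null(res)) {
    ma <- lp_mono_content(a); mb <- lp_mono_content(b)
    return(mono_gcd(ma, mb))
  }
  lp_primitive(res)
}

mono_gcd <- function(ma, mb) {
  vars <- intersect(ma$vars, mb$vars)
  if (length(vars) == 0) return(lp_const(1))
  ea <- ma$expo[1, match(vars, ma$vars)]
  eb <- mb$expo[1, match(vars, mb$vars)]
  e <- pmin(ea, eb)
  if (all(e == 0)) return(lp_const(1))
  lp_make(vars[e > 0], matrix(e[e > 0], 1), 1, 1)
}

# deterministic projection points for the univariate gcd-degree probe;
# small values keep the exact integer arithmetic within range
PROJ_POINTS <- c(2, 3, 5, 7, 11, 13)

proj_point_env <- function(vars) {
  stats::setNames(as.list(PROJ_POINTS[(seq_along(vars) - 1L) %% length(PROJ_POINTS) + 1L]),
                  vars)
}

# exact univariate gcd degree of the projections of a and b onto variable v
# (all other variables replaced by fixed small integers).  The projected gcd
# degree is an upper bound for deg_v(gcd(a, b)): a result of 0 proves the
# true gcd is free of v.  Overflow or degeneracy returns NA (inconclusive).
uni_gcd_degree <- function(a, b, v) {
  # one shared point assignment: a factor common to a and b must project to
  # a common univariate factor only if both see the same substitution
  pts <- proj_point_env(setdiff(sort(union(a$vars, b$vars)), v))
  pa <- tryCatch(lp_subs_int(a, pts), error = function(e) NULL)
  pb <- tryCatch(lp_subs_int(b, pts), error = function(e) NULL)
  if (is.null(pa) || is.null(pb) || lp_is_zero(pa) || lp_is_zero(pb)) return(NA_integer_)
  ca <- uni_coefvec(pa, v); cb <- uni_coefvec(pb, v)
  if (is.null(ca) || is.null(cb)) return(NA_integer_)
  g <- tryCatch(uni_gcd(ca, cb), error = function(e) NULL)
  if (is.null(g)) return(NA_integer_)
  length(g) - 1L
}

uni_coefvec <- function(p, v) {
  # p must involve only v; coefficients are cleared to exact integers
  # (uni_gcd's primitive-part arithmetic assumes integer input)
  if (!all(p$vars %in% v)) return(NULL)
  l <- 1
  for (d in p$den) l <- l * d / int_gcd(l, d)
  if (l > MAXINT) return(NULL)
  vals <- p$num * (l / p$den)
  if (any(abs(vals) > MAXINT)) return(NULL)
  co <- numeric(lp_degree(p, v) + 1)
  if (length(p$vars) == 0) { co[1] <- vals; return(co) }
  co[p$expo[, 1] + 1] <- vals
  co
}

# exact univariate gcd (integer coefficient vectors, low degree first) via
# primitive pseudo-remainder Euclid; coefficients are doubles holding
# integers, renormalized to primitive after every remainder
uni_gcd <- function(a, b) {
  trim <- function(x) { while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]; x }
  prim <- function(x) {
    g <- 0; for (c in x) if (c != 0) g <- int_gcd(g, round(c))
    if (g > 1) x / g else x
  }
  is0 <- function(x) length(x) == 1 && x[1] == 0
  a <- prim(trim(a)); b <- prim(trim(b))
  if (is0(a)) return(b)
  while (!is0(b)) {
    if (length(a) < length(b)) { t <- a; a <- b; b <- t; next }
    r <- a
    while (!is0(r) && length(r) >= length(b)) {
      shift <- length(r) - length(b)
      lead_r <- r[length(r)]
      r <- r * b[length(b)]
      r[(shift + 1):length(r)] <- r[(shift + 1):length(r)] - lead_r * b
      if (any(abs(r) > MAXINT)) stop("overflow", call. = FALSE)
      r <- prim(trim(r))
    }
    a <- b; b <- r
  }
  prim(a)
}

lp_gcd_rec <- function(a, b, env, budget) {
  # the budget counts term-operations, so a failed gcd gives up quickly
  env$steps <- env$steps + length(a$num) + length(b$num)
  if (env$steps > budget)
    stop(structure(class = c("lpoly_budget", "error", "condition"),
                   list(message = "gcd budget", call = NULL)))
  if (lp_is_zero(a)) return(b)
  if (lp_is_zero(b)) return(a)
  if (lp_is_const(a) || lp_is_const(b)) return(lp_const(1))
  ma <- lp_mono_content(a); mb <- lp_mono_content(b)
  mg <- mono_gcd(ma, mb)
  a <- lp_strip_mono(a, ma); b <- lp_strip_mono(b, mb)
  if (lp_is_const(a) || lp_is_const(b)) return(mg)
  vars <- intersect(a$vars, b$vars)
  if (length(vars) == 0) return(mg)
  # projection probe: variables whose projected univariate gcd is constant
  # cannot appear in the gcd; if none remains the gcd is the monomial part
  pdeg <- vapply(vars, function(v) uni_gcd_degree(a, b, v), integer(1))
  vars <- vars[is.na(pdeg) | pdeg > 0]
  if (length(vars) == 0) return(mg)
  # main variable: smallest (projected or max) degree for a short PRS
  degs <- vapply(vars, function(v) max(lp_degree(a, v), lp_degree(b, v)), numeric(1))
  v <- vars[order(degs, vars)][1]
  # univariate-in-v representation with polynomial coefficients
  ca <- lp_coef_split(a, v); cb <- lp_coef_split(b, v)
  cont_a <- Reduce(function(x, y) lp_gcd_rec(x, y, env, budget), ca)
  cont_b <- Reduce(function(x, y) lp_gcd_rec(x, y, env, budget), cb)
  cont_g <- lp_gcd_rec(cont_a, cont_b, env, budget)
  pa <- lp_primitive(lp_divexact(a, cont_a))
  pb <- lp_primitive(lp_divexact(b, cont_b))
  # primitive Euclid via pseudo-remainders in v
  f <- pa; g <- pb
  if (lp_degree(f, v) < lp_degree(g, v)) { t <- f; f <- g; g <- t }
  repeat {
    if (env$steps > budget)
      stop(structure(class = c("lpoly_budget", "error", "condition"),
                     list(message = "gcd budget", call = NULL)))
    if (lp_is_zero(g)) break
    r <- lp_prem(f, g, v, env, budget)
    f <- g
    g <- if (lp_is_zero(r)) r else lp_primitive(lp_strip_content(r, v, env, budget))
  }
  if (lp_degree(f, v) == 0 && lp_is_const(f)) return(mg_mul(mg, cont_g))
  if (lp_degree(f, v) == 0) {
    # gcd free of v: it divides both primitive parts only if constant
    return(mg_mul(mg, cont_g))
  }
  mg_mul(mg, lp_mul(cont_g, lp_primitive(f)))
}

mg_mul <- function(a, b) lp_mul(a, b)

# divide out the content (gcd of v-coefficients) of r
lp_strip_content <- function(r, v, env, budget) {
  cs <- lp_coef_split(r, v)
  cs <- Filter(Negate(lp_is_zero), cs)
  if (length(cs) == 1) return(r)
  cont <- Reduce(function(x, y) lp_gcd_rec(x, y, env, budget), cs)
  if (lp_is_const(cont)) return(r)
  lp_divexact(r, cont)
}

# pseudo-remainder of f by g in variable v
lp_prem <- function(f, g, v, env = NULL, budget = Inf) {
  df <- lp_degree(f, v); dg <- lp_degree(g, v)
  if (dg == 0) return(lp_zero())
  if (df < dg) return(f)
  cg <- lp_coef_split(g, v)
  lcg <- cg[[dg + 1]]
  while (!lp_is_zero(f) && (df <- lp_degree(f, v)) >= dg) {
    if (!is.null(env)) {
      env$steps <- env$steps + length(f$num) + length(lcg$num)
      if (env$steps > budget)
        stop(structure(class = c("lpoly_budget", "error", "condition"),
                       list(message = "gcd budget", call = NULL)))
    }
    cf <- lp_coef_split(f, v)
    lcf <- cf[[df + 1]]
    if (lp_is_zero(lcf)) break
    shift <- lp_var(v, df - dg)
    f <- lp_sub(lp_mul(f, lcg), lp_mul(lp_mul(lcf, shift), g))
    # only the primitive part matters for gcd purposes; stripping the
    # rational content each round keeps the exact integers bounded
    if (!lp_is_zero(f)) f <- lp_primitive(f)
    if (!lp_is_zero(f) && lp_degree(f, v) == df) {
      # no degree drop means leading terms did not cancel exactly; should not
      # happen with exact arithmetic
      stop("pseudo-division failed to reduce degree", call. = FALSE)
    }
  }
  f
}

# gcd of a list of polynomials, with early exit once the gcd is constant
lp_gcd_list <- function(ps, budget = 2000L) {
  ps <- Filter(Negate(lp_is_zero), ps)
  if (length(ps) == 0) return(lp_zero())
  sizes <- vapply(ps, function(p) length(p$num), numeric(1))
  ps <- ps[order(sizes)]
  g <- lp_primitive(ps[[1]])
  for (p in ps[-1]) {
    if (lp_is_const(g)) break
    g <- lp_gcd(g, p, budget)
  }
  g
}

# ------------------------------------------------------------------------
# rendering and parsing

fmt_rat <- function(num, den) {
  if (den == 1) format(num, scientific = FALSE) else paste0(format(num, scientific = FALSE), "/", format(den, scientific = FALSE))
}

lp_to_string <- function(a) {
  if (lp_is_zero(a)) return("0")
  out <- character(length(a$num))
  for (i in seq_along(a$num)) {
    e <- a$expo[i, ]
    mono <- character(0)
    for (j in seq_along(a$vars)) {
      if (e[j] == 1) mono <- c(mono, a$vars[j])
      else if (e[j] > 1) mono <- c(mono, paste0(a$vars[j], "^", e[j]))
    }
    co <- abs(a$num[i])
    cstr <- fmt_rat(co, a$den[i])
    term <- if (length(mono) == 0) cstr
            else if (cstr == "1") paste(mono, collapse = "*")
            else paste(c(cstr, mono), collapse = "*")
    out[i] <- term
  }
  signs <- ifelse(a$num >= 0, "+", "-")
  res <- out[1]
  if (a$num[1] < 0) res <- paste0("-", res)
  for (i in seq_along(out)[-1]) {
    res <- paste(res, signs[i], out[i])
  }
  res
}

#' @export
print.lpoly <- function(x, ...) {
  cat(lp_to_string(x), "\n")
  invisible(x)
}

lp_equal <- function(a, b) lp_is_zero(lp_sub(a, b))

# decimal string -> exact rational (e.g. "0.7" -> 7/10)
dec_to_rat <- function(txt) {
  if (grepl("e|E", txt)) {
    v <- as.numeric(txt)
    return(dec_to_rat(format(v, scientific = FALSE, trim = TRUE)))
  }
  if (!grepl("\\.", txt)) return(list(num = as.numeric(txt), den = 1))
  parts <- strsplit(txt, ".", fixed = TRUE)[[1]]
  frac <- parts[2]
  den <- 10^nchar(frac)
  num <- as.numeric(parts[1]) * den + as.numeric(frac) * sign_of(parts[1])
  rat_reduce(num, den)
}

sign_of <- function(txt) if (grepl("^-", txt)) -1 else 1

# parse an arithmetic expression string into a rational function (see ratfun.R)
parse_expression <- function(txt) {
  e <- tryCatch(str2lang(txt), error = function(err)
    stop(sprintf("cannot parse expression '%s'", txt), call. = FALSE))
  expr_to_rf(e)
}

expr_to_rf <- function(e) {
  if (is.numeric(e)) {
    r <- dec_to_rat(format(e, scientific = FALSE, trim = TRUE, digits = 15))
    return(rf_from_poly(lp_const(r$num, r$den)))
  }
  if (is.name(e)) return(rf_from_poly(lp_var(as.character(e))))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_to_rf(e[[2]]))
    if (op == "-" && length(e) == 2) return(rf_neg(expr_to_rf(e[[2]])))
    if (op == "+" && length(e) == 2) return(expr_to_rf(e[[2]]))
    a <- expr_to_rf(e[[2]])
    if (op == "^") {
      k <- e[[3]]
      if (!is.numeric(k) || k != round(k) || k < 0)
        stop("only non-negative integer powers are supported", call. = FALSE)
      return(rf_pow(a, as.integer(k)))
    }
    b <- expr_to_rf(e[[3]])
    switch(op,
           "+" = rf_add(a, b),
           "-" = rf_sub(a, b),
           "*" = rf_mul(a, b),
           "/" = rf_div(a, b),
           stop(sprintf("unsupported operator '%s'", op), call. = FALSE))
  } else {
    stop("unsupported expression element", call. = FALSE)
  }
}
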