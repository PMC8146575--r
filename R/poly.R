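# Exact sparse multivariate polynomials over the rationals.
#
# Coefficients are rationals held as integer-valued doubles (num, den),
# gcd-reduced after every operation; all quantities arising from Bell
# polynomials up to order ~12 stay far below 2^53, so arithmetic is exact.
# Symbols are plain names ("tau", "D1", ..., "M1", ...); a polynomial is a
# named list of terms keyed by their canonical monomial string.

.km_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  if (num == 0) return(c(0, 1))
  g <- .km_gcd(num, den)
  c(num / g, den / g)
}

.rat_add <- function(a, b) .rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
.rat_mul <- function(a, b) .rat(a[1] * b[1], a[2] * b[2])

# canonical symbol rank: tau first, then by alphabetic prefix and numeric index
.sym_rank <- function(syms) {
  pre <- sub("[0-9]+$", "", syms)
  idx <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", syms)))
  idx[is.na(idx)] <- 0
  first <- vapply(pre, function(s) utf8ToInt(substr(s, 1, 1)), numeric(1))
  ifelse(syms == "tau", -1e9, first * 1e6 + idx)
}

.pow_canon <- function(pow) {
  pow <- pow[pow != 0]
  if (!length(pow)) return(pow)
  pow[order(.sym_rank(names(pow)))]
}

.pow_key <- function(pow) {
  if (!length(pow)) return("1")
  paste0(names(pow), "^", pow, collapse = "*")
}

.km_term <- function(num, den, pow) list(num = num, den = den, pow = .pow_canon(pow))

.km_poly_new <- function(terms) {
  structure(list(terms = terms), class = "km_poly")
}

.km_normalize <- function(terms) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in terms) {
    if (t$num == 0) next
    k <- .pow_key(t$pow)
    prev <- env[[k]]
    if (is.null(prev)) {
      env[[k]] <- t
    } else {
      r <- .rat_add(c(prev$num, prev$den), c(t$num, t$den))
      prev$num <- r[1]; prev$den <- r[2]
      env[[k]] <- prev
    }
  }
  out <- Filter(function(t) t$num != 0, as.list(env, sorted = TRUE))
  .km_poly_new(out)
}

#' Create a symbolic atom
#'
#' Builds the exact-arithmetic polynomial consisting of a single symbol, for
#' use with the Bell-polynomial and expansion machinery. Symbols are free-form
#' names; the expansions use `"tau"`, `"D1"`...`"Dn"` and `"M1"`...`"Mn"`.
#'
#' @param name symbol name, e.g. `"D2"`.
#' @return A `km_poly` object. `km_poly` objects support `+`, `-`, `*`, `^`
#'   (non-negative integer exponent) and division by integer scalars, all in
#'   exact rational arithmetic.
#' @examples
#' (2 * km_sym("tau") * km_sym("D2") + km_sym("tau")^2 * km_sym("D1")^2)
#' @export
km_sym <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .km_normalize(list(.km_term(1, 1, stats::setNames(1, name))))
}

#' Create an exact rational constant
#'
#' @param num integer numerator.
#' @param den integer denominator (default 1).
#' @return A constant `km_poly`.
#' @export
km_const <- function(num, den = 1) {
  stopifnot(num == round(num), den == round(den))
  r <- .rat(num, den)
  if (r[1] == 0) return(.km_poly_new(list()))
  .km_normalize(list(.km_term(r[1], r[2], stats::setNames(numeric(0), character(0)))))
}

.as_km_poly <- function(x) {
  if (inherits(x, "km_poly")) return(x)
  if (is.numeric(x) && length(x) == 1L && x == round(x)) return(km_const(x))
  stop("cannot coerce to km_poly: ", deparse(substitute(x)))
}

.poly_add <- function(p, q) .km_normalize(c(p$terms, q$terms))

.poly_neg <- function(p) {
  .km_poly_new(lapply(p$terms, function(t) { t$num <- -t$num; t }))
}

.poly_mul <- function(p, q) {
  terms <- list()
  for (a in p$terms) for (b in q$terms) {
    r <- .rat_mul(c(a$num, a$den), c(b$num, b$den))
    pow <- a$pow
    for (s in names(b$pow)) pow[s] <- (if (s %in% names(pow)) pow[s] else 0) + b$pow[[s]]
    terms[[length(terms) + 1L]] <- .km_term(r[1], r[2], pow)
  }
  .km_normalize(terms)
}

.poly_pow <- function(p, k) {
  stopifnot(k >= 0, k == round(k))
  out <- km_const(1)
  while (k > 0) { out <- .poly_mul(out, p); k <- k - 1 }
  out
}

#' @export
Ops.km_poly <- function(e1, e2) {
  if (.Generic %in% c("==", "!=")) {
    eq <- km_poly_equal(.as_km_poly(e1), .as_km_poly(e2))
    return(if (.Generic == "==") eq else !eq)
  }
  if (missing(e2)) {
    if (.Generic == "-") return(.poly_neg(e1))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operator for km_poly: ", .Generic)
  }
  switch(.Generic,
    "+" = .poly_add(.as_km_poly(e1), .as_km_poly(e2)),
    "-" = .poly_add(.as_km_poly(e1), .poly_neg(.as_km_poly(e2))),
    "*" = .poly_mul(.as_km_poly(e1), .as_km_poly(e2)),
    "^" = {
      stopifnot(is.numeric(e2), length(e2) == 1L)
      .poly_pow(e1, e2)
    },
    "/" = {
      stopifnot(is.numeric(e2), length(e2) == 1L, e2 == round(e2), e2 != 0)
      .poly_mul(e1, km_const(1, e2))
    },
    stop("unsupported operator for km_poly: ", .Generic)
  )
}

#' Test two exact polynomials for identity
#'
#' @param p,q `km_poly` objects.
#' @return `TRUE` if all terms agree exactly.
#' @export
km_poly_equal <- function(p, q) {
  d <- .poly_add(p, .poly_neg(q))
  length(d$terms) == 0L
}

#' Evaluate an exact polynomial numerically
#'
#' @param p a `km_poly`.
#' @param values named numeric vector or list giving a value for every symbol
#'   occurring in `p` (including `"tau"` where present).
#' @return numeric scalar.
#' @export
km_eval <- function(p, values) {
  values <- unlist(values)
  tot <- 0
  for (t in p$terms) {
    v <- t$num / t$den
    for (s in names(t$pow)) {
      if (!s %in% names(values)) stop("no value supplied for symbol ", s)
      v <- v * values[[s]]^t$pow[[s]]
    }
    tot <- tot + v
  }
  tot
}

#' Substitute polynomials for symbols
#'
#' Replaces each symbol named in `subs` by the corresponding `km_poly`;
#' symbols not named are left untouched. Used e.g. to verify that the forward
#' moment expansion composed with the reciprocal inversion is the identity.
#'
#' @param p a `km_poly`.
#' @param subs named list of `km_poly` replacements.
#' @return A `km_poly`.
#' @export
km_substitute <- function(p, subs) {
  out <- km_const(0)
  for (t in p$terms) {
    term <- .km_normalize(list(.km_term(t$num, t$den, stats::setNames(numeric(0), character(0)))))
    for (s in names(t$pow)) {
      rep <- if (s %in% names(subs)) subs[[s]] else km_sym(s)
      term <- .poly_mul(term, .poly_pow(rep, t$pow[[s]]))
    }
    out <- .poly_add(out, term)
  }
  out
}

# term sort order: graded by tau power, then total degree in the remaining
# symbols, then lexicographic on the multiset of symbol indices (so D1*D3
# precedes D2^2 within one grade, and M2 precedes M1^2)
.term_order <- function(terms) {
  if (!length(terms)) return(integer(0))
  keys <- lapply(terms, function(t) {
    tau <- if ("tau" %in% names(t$pow)) t$pow[["tau"]] else 0
    rest <- t$pow[names(t$pow) != "tau"]
    reps <- rep(.sym_rank(names(rest)), times = rest)
    list(tau = tau, deg = sum(rest), reps = reps)
  })
  maxlen <- max(vapply(keys, function(k) length(k$reps), 1L))
  mat <- t(vapply(keys, function(k) {
    c(k$tau, k$deg, k$reps, rep(Inf, maxlen - length(k$reps)))
  }, numeric(2 + maxlen)))
  do.call(order, as.data.frame(mat))
}

.coef_str <- function(num, den) {
  if (den == 1) format(num, scientific = FALSE) else
    paste0(format(num, scientific = FALSE), "/", format(den, scientific = FALSE))
}

.term_str <- function(t, strip_sign = FALSE) {
  num <- t$num
  if (strip_sign) num <- abs(num)
  facs <- character(0)
  if (!(abs(num) == 1 && t$den == 1) || !length(t$pow)) {
    facs <- .coef_str(num, t$den)
  } else if (num < 0) {
    facs <- "-1" # only reached when not stripping sign and coef is -1
  }
  for (s in names(t$pow)) {
    e <- t$pow[[s]]
    facs <- c(facs, if (e == 1) s else paste0(s, "^", e))
  }
  # a leading "-1" coefficient with symbols renders as "-sym"
  if (length(facs) > 1 && facs[1] == "-1") {
    facs <- facs[-1]
    return(paste0("-", paste(facs, collapse = "*")))
  }
  paste(facs, collapse = "*")
}

.poly_plain <- function(p) {
  if (!length(p$terms)) return("0")
  terms <- p$terms[.term_order(p$terms)]
  out <- .term_str(terms[[1L]])
  if (length(terms) > 1L) for (t in terms[-1L]) {
    sep <- if (t$num < 0) " - " else " + "
    out <- paste0(out, sep, .term_str(t, strip_sign = TRUE))
  }
  out
}

.sym_latex <- function(s) {
  if (s == "tau") return("\\tau")
  pre <- sub("[0-9]+$", "", s)
  idx <- sub("^[^0-9]*", "", s)
  if (nzchar(idx)) paste0(pre, "_{", idx, "}") else s
}

.term_latex <- function(t, strip_sign = FALSE) {
  num <- if (strip_sign) abs(t$num) else t$num
  coef <- if (t$den == 1) {
    if (abs(num) == 1 && length(t$pow)) (if (num < 0) "-" else "") else format(num, scientific = FALSE)
  } else {
    paste0(if (num < 0) "-" else "", "\\frac{", format(abs(num), scientific = FALSE),
           "}{", format(t$den, scientific = FALSE), "}")
  }
  facs <- vapply(names(t$pow), function(s) {
    e <- t$pow[[s]]
    if (e == 1) .sym_latex(s) else paste0(.sym_latex(s), "^{", e, "}")
  }, character(1))
  paste0(coef, if (nzchar(coef) && !endsWith(coef, "-")) " " else "", paste(facs, collapse = " "))
}

.poly_latex <- function(p) {
  if (!length(p$terms)) return("0")
  terms <- p$terms[.term_order(p$terms)]
  out <- .term_latex(terms[[1L]])
  if (length(terms) > 1L) for (t in terms[-1L]) {
    sep <- if (t$num < 0) " - " else " + "
    out <- paste0(out, sep, .term_latex(t, strip_sign = TRUE))
  }
  out
}

#' @export
format.km_poly <- function(x, ...) .poly_plain(x)

#' @export
print.km_poly <- function(x, ...) {
  cat(.poly_plain(x), "\n")
  invisible(x)
}
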