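# Formal power-series expansion of the exponentiated Kramers-Moyal operator,
# including terms with spatial derivatives of the KM coefficients.
#
# The k-th order contribution to M_n(x', tau) is tau^k/k! times the k-fold
# adjoint action evaluated at x = x':
#   M_n = sum_k tau^k/k! [ (L+)^k (x - x')^n ]_{x = x'},
#   L+ f = sum_{m=1}^{N} D_m(x) d^m f / dx^m,
# obtained from integrating the operator products by parts against the delta
# initial condition. Each surviving term is a product of (possibly
# differentiated) KM coefficients D_p^{(d)} with an exact rational
# coefficient; the infinite operator sum is truncated at D_N (D_p = 0 for
# p > N) and derivative orders are capped at max_deriv.

# internal working-term representation:
#   list(num, den, xpow, fac) with fac an integer matrix, columns (p, d)
.fac_key <- function(fac) {
  if (!nrow(fac)) return("")
  o <- order(fac[, 1], fac[, 2])
  paste(fac[o, 1], fac[o, 2], sep = "'", collapse = ",")
}

.op_normalize <- function(terms) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in terms) {
    if (t$num == 0) next
    key <- paste0(t$xpow, "|", .fac_key(t$fac))
    prev <- env[[key]]
    if (is.null(prev)) {
      o <- order(t$fac[, 1], t$fac[, 2])
      t$fac <- t$fac[o, , drop = FALSE]
      env[[key]] <- t
    } else {
      r <- .rat_add(c(prev$num, prev$den), c(t$num, t$den))
      prev$num <- r[1]; prev$den <- r[2]
      env[[key]] <- prev
    }
  }
  Filter(function(t) t$num != 0, as.list(env, sorted = TRUE))
}

# d/dx of a term: product rule over the (x - x')^p factor and every D factor
.op_diff <- function(terms) {
  out <- list()
  for (t in terms) {
    if (t$xpow > 0) {
      s <- t
      s$num <- s$num * s$xpow
      s$xpow <- s$xpow - 1L
      out[[length(out) + 1L]] <- s
    }
    if (nrow(t$fac)) for (i in seq_len(nrow(t$fac))) {
      s <- t
      s$fac[i, 2] <- s$fac[i, 2] + 1L
      out[[length(out) + 1L]] <- s
    }
  }
  .op_normalize(out)
}

# L+ applied to a list of terms, truncating the operator sum at N
.op_adjoint <- function(terms, N) {
  out <- list()
  dcache <- list()
  dcache[[1]] <- .op_diff(terms)
  for (m in seq_len(N)) {
    if (m > 1) dcache[[m]] <- .op_diff(dcache[[m - 1]])
    for (t in dcache[[m]]) {
      t$fac <- rbind(t$fac, c(m, 0L))
      out[[length(out) + 1L]] <- t
    }
  }
  .op_normalize(out)
}

#' Expand conditional moments with KM-coefficient derivative terms
#'
#' Performs the formal k-fold application of the truncated Kramers-Moyal
#' operator to the delta initial condition (by symbolic integration by
#' parts), for `k = 1, ..., order`, and collects every surviving term of the
#' n-th conditional moment -- including the terms containing spatial
#' derivatives `D_p^{(d)}` that the closed-form Bell inversion neglects.
#'
#' @param n conditional-moment order, positive integer.
#' @param order highest power of `tau` retained, `>= 1`.
#' @param truncation_N highest KM coefficient kept (`D_p = 0` for
#'   `p > truncation_N`).
#' @param max_deriv cap on the derivative order `d`; terms whose factors
#'   would exceed it are dropped and the result is marked truncated.
#' @return An object of class `km_operator_terms`: a list of terms, each with
#'   elements `num`, `den` (exact rational coefficient including the `1/k!`),
#'   `tau_power = k`, and `factors`, an integer matrix whose rows `(p, d)`
#'   denote a factor `D_p^{(d)}`. Attribute `truncated` reports whether the
#'   derivative cap removed any term. Every term satisfies
#'   `sum(p) - sum(d) == n`.
#' @examples
#' # M1 to second order: tau*D1 + tau^2/2 * (D1*D1' + D2*D1'' + ...)
#' expand_with_derivatives(1, order = 2, truncation_N = 2)
#' @export
expand_with_derivatives <- function(n, order, truncation_N, max_deriv = Inf) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (truncation_N < 1) stop("truncation_N must be >= 1")
  f <- list(list(num = 1, den = 1, xpow = as.integer(n),
                 fac = matrix(integer(0), 0, 2)))
  collected <- list()
  truncated <- FALSE
  for (k in seq_len(order)) {
    f <- .op_adjoint(f, truncation_N)
    # a term can lower its (x - x')^p power by at most truncation_N per
    # remaining operator application; anything above that bound can never
    # survive the evaluation at x = x', so drop it now
    reach <- (order - k) * truncation_N
    f <- Filter(function(t) t$xpow <= reach, f)
    if (is.finite(max_deriv)) {
      keep <- vapply(f, function(t) !nrow(t$fac) || max(t$fac[, 2]) <= max_deriv,
                     logical(1))
      if (any(!keep)) truncated <- TRUE
      f <- f[keep]
    }
    for (t in f) {
      if (t$xpow == 0L) { # survives evaluation at x = x'
        r <- .rat_mul(c(t$num, t$den), c(1, factorial(k)))
        collected[[length(collected) + 1L]] <- list(
          num = r[1], den = r[2], tau_power = as.integer(k),
          factors = t$fac)
      }
    }
  }
  structure(collected, class = "km_operator_terms",
            truncated = truncated, n = n, order = order,
            truncation_N = truncation_N, max_deriv = max_deriv)
}

#' Closed form of the second-order derivative terms
#'
#' Builds the second-order derivative contribution to the n-th conditional
#' moment, `n! * tau^2/2 * sum_{s=0}^{n-1} sum_{m=s+1}^{N} choose(m, s)
#' D_{n-s}^{(m-s)} D_m` (the factor `n!` multiplies the whole bracketed
#' second-order approximation), directly from its closed form, truncated at
#' `D_p = 0` for `p > N`; independent reference for the operator expansion.
#'
#' @param n conditional-moment order.
#' @param truncation_N highest KM coefficient kept.
#' @return A `km_operator_terms` object with `tau_power = 2` terms only.
#' @export
phi_second_order <- function(n, truncation_N) {
  out <- list()
  for (s in 0:(n - 1)) {
    if (n - s > truncation_N) next
    if (s + 1 > truncation_N) next
    for (m in seq.int(s + 1, truncation_N)) {
      r <- .rat(factorial(n) * choose(m, s), 2)
      out[[length(out) + 1L]] <- list(
        num = r[1], den = r[2], tau_power = 2L,
        factors = {
          fac <- rbind(c(n - s, m - s), c(m, 0L))
          fac[order(fac[, 1], fac[, 2]), , drop = FALSE]
        })
    }
  }
  # merge identical factor multisets
  merged <- list()
  for (t in out) {
    key <- .fac_key(t$factors)
    if (is.null(merged[[key]])) merged[[key]] <- t
    else {
      r <- .rat_add(c(merged[[key]]$num, merged[[key]]$den), c(t$num, t$den))
      merged[[key]]$num <- r[1]; merged[[key]]$den <- r[2]
    }
  }
  structure(unname(merged), class = "km_operator_terms",
            truncated = FALSE, n = n, order = 2L,
            truncation_N = truncation_N, max_deriv = Inf)
}

#' Keep only derivative-free or derivative-bearing operator terms
#'
#' @param terms a `km_operator_terms` object.
#' @param derivatives if `FALSE`, keep terms with all derivative orders zero;
#'   if `TRUE`, keep terms containing at least one derivative.
#' @return A filtered `km_operator_terms` object.
#' @export
operator_terms_filter <- function(terms, derivatives) {
  keep <- vapply(terms, function(t) {
    has <- nrow(t$factors) > 0 && any(t$factors[, 2] > 0)
    if (derivatives) has else !has
  }, logical(1))
  structure(unclass(terms)[keep], class = "km_operator_terms",
            truncated = attr(terms, "truncated"), n = attr(terms, "n"),
            order = attr(terms, "order"),
            truncation_N = attr(terms, "truncation_N"),
            max_deriv = attr(terms, "max_deriv"))
}

# convert derivative-free operator terms to an exact km_poly in tau, D1..;
# errors if any term carries a derivative
operator_terms_poly <- function(terms) {
  acc <- km_const(0)
  for (t in terms) {
    if (nrow(t$factors) && any(t$factors[, 2] > 0)) {
      stop("terms contain derivatives; filter first")
    }
    mono <- km_const(t$num, t$den) * km_sym("tau")^t$tau_power
    if (nrow(t$factors)) for (i in seq_len(nrow(t$factors))) {
      mono <- mono * km_sym(paste0("D", t$factors[i, 1]))
    }
    acc <- acc + mono
  }
  acc
}

.factor_str <- function(fac, latex = FALSE) {
  if (!nrow(fac)) return("1")
  paste(apply(fac, 1, function(f) {
    if (latex) {
      base <- paste0("D_{", f[1], "}")
      if (f[2] > 0) paste0(base, "^{(", f[2], ")}") else base
    } else {
      base <- paste0("D", f[1])
      if (f[2] > 0) paste0(base, "^(", f[2], ")") else base
    }
  }), collapse = if (latex) " " else "*")
}

.render_operator <- function(x, format = "plain") {
  latex <- format == "latex"
  if (!length(x)) return("0")
  key <- vapply(x, function(t) t$tau_power * 1e6 +
                  nrow(t$factors) + sum(t$factors[, 1]) / 100, numeric(1))
  parts <- vapply(unclass(x)[order(key)], function(t) {
    coef <- if (latex) {
      if (t$den == 1) format(t$num, scientific = FALSE)
      else paste0("\\frac{", format(t$num, scientific = FALSE), "}{",
                  format(t$den, scientific = FALSE), "}")
    } else .coef_str(t$num, t$den)
    tau <- if (latex) {
      if (t$tau_power == 1) "\\tau" else paste0("\\tau^{", t$tau_power, "}")
    } else {
      if (t$tau_power == 1) "tau" else paste0("tau^", t$tau_power)
    }
    paste0("(", coef, ")", if (latex) " " else "*", tau,
           if (latex) " " else "*", .factor_str(t$factors, latex))
  }, character(1))
  paste(parts, collapse = " + ")
}

#' @export
print.km_operator_terms <- function(x, ...) {
  cat(sprintf("operator expansion of M%d to order tau^%d (D truncated at N=%d)\n",
              attr(x, "n"), attr(x, "order"), attr(x, "truncation_N")))
  if (isTRUE(attr(x, "truncated"))) cat("note: derivative cap removed terms\n")
  cat(.render_operator(x), "\n")
  invisible(x)
}

#' Verify the subscript/superscript bookkeeping of operator terms
#'
#' For every term, the sum of coefficient orders (subscripts) minus the sum
#' of derivative orders (superscripts) must equal the order `n` of the
#' conditional moment being expanded.
#'
#' @param terms a `km_operator_terms` object.
#' @return logical vector, one entry per term.
#' @export
operator_terms_bookkeeping <- function(terms) {
  n <- attr(terms, "n")
  vapply(terms, function(t) {
    sum(t$factors[, 1]) - sum(t$factors[, 2]) == n
  }, logical(1))
}
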