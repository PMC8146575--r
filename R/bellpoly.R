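# Partial ordinary and partial exponential Bell polynomials.
#
# Both are sums over the integer-partition solutions (j_1, ..., j_{n-m+1}) of
#   sum_r j_r = m   and   sum_r r * j_r = n,
# where j_r counts parts of size r. They differ only in the factorial weights:
#   ordinary:     m! / prod(j_r!)                 * prod x_r^{j_r}
#   exponential:  n! / prod(j_r! * (r!)^{j_r})    * prod x_r^{j_r}
# and are linked by Bhat_{n,m}(x) = (m!/n!) B_{n,m}(1! x_1, 2! x_2, ...).

#' Enumerate partitions under the Bell constraints
#'
#' Lists every multiplicity vector `(j_1, ..., j_{n-m+1})` with
#' `sum(j) == m` parts and total weight `sum(r * j_r) == n`, i.e. the
#' partitions of `n` into exactly `m` parts, encoded by part-size
#' multiplicities. The order is canonical: lexicographically descending on
#' `(j_1, j_2, ...)`.
#'
#' @param n total weight (positive integer).
#' @param m number of parts, `1 <= m <= n`.
#' @return A list of integer vectors, each of length `n - m + 1`.
#' @examples
#' enumerate_partitions(4, 2) # 4 = 1+3 and 4 = 2+2
#' @export
enumerate_partitions <- function(n, m) {
  if (length(n) != 1L || length(m) != 1L || !is.finite(n) || !is.finite(m) ||
      n != round(n) || m != round(m) || n < 1 || m < 1) {
    stop("n and m must be positive integers")
  }
  if (m > n) stop("m must not exceed n")
  len <- n - m + 1L
  out <- list()
  # fill j_1..j_len recursively, largest j_1 first -> descending lex order
  rec <- function(r, j, parts_left, weight_left) {
    if (r > len) {
      if (parts_left == 0L && weight_left == 0L) out[[length(out) + 1L]] <<- j
      return(invisible(NULL))
    }
    # j_r at most parts_left and at most weight_left / r
    jmax <- min(parts_left, weight_left %/% r)
    for (jr in seq.int(jmax, 0L)) {
      j[r] <- jr
      rec(r + 1L, j, parts_left - jr, weight_left - jr * r)
    }
  }
  rec(1L, integer(len), as.integer(m), as.integer(n))
  out
}

.bell_sum <- function(n, m, inputs, coef_fun) {
  len <- n - m + 1L
  if (length(inputs) != len) {
    stop("inputs must have length n - m + 1 = ", len)
  }
  symbolic <- any(vapply(inputs, inherits, logical(1), "km_poly"))
  parts <- enumerate_partitions(n, m)
  acc <- if (symbolic) km_const(0) else 0
  for (j in parts) {
    coef <- coef_fun(j)
    term <- if (symbolic) km_const(coef) else coef
    for (r in seq_len(len)) {
      if (j[r] > 0) {
        x <- if (symbolic) .as_km_poly(inputs[[r]]) else inputs[[r]]
        term <- term * x^j[r]
      }
    }
    acc <- acc + term
  }
  acc
}

#' Partial ordinary Bell polynomial
#'
#' Evaluates `Bhat_{n,m}(x_1, ..., x_{n-m+1})`, the sum over partitions of
#' `n` into `m` parts of `m!/prod(j_r!) * prod(x_r^{j_r})`. Inputs may be
#' numeric or symbolic ([km_sym()] polynomials); in the symbolic case the
#' result is exact.
#'
#' @param n total weight.
#' @param m number of parts.
#' @param inputs list or numeric vector of length `n - m + 1`.
#' @return numeric scalar or `km_poly`, matching the input kind.
#' @examples
#' ordinary_bell(4, 2, c(2, 3, 5)) # 2*x1*x3 + x2^2 = 29
#' @export
ordinary_bell <- function(n, m, inputs) {
  .bell_sum(n, m, as.list(inputs), function(j) factorial(m) / prod(factorial(j)))
}

#' Partial exponential Bell polynomial
#'
#' Evaluates `B_{n,m}(x_1, ..., x_{n-m+1})`, the sum over partitions of `n`
#' into `m` parts of `n! / (prod(j_r!) * prod((r!)^{j_r})) * prod(x_r^{j_r})`.
#'
#' @inheritParams ordinary_bell
#' @return numeric scalar or `km_poly`, matching the input kind.
#' @examples
#' exponential_bell(3, 2, c(1, 1)) # 3*x1*x2 = 3
#' @export
exponential_bell <- function(n, m, inputs) {
  .bell_sum(n, m, as.list(inputs), function(j) {
    r <- seq_along(j)
    factorial(n) / prod(factorial(j) * factorial(r)^j)
  })
}
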