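# Exact relations between conditional moments M_n(x', tau) and Kramers-Moyal
# coefficients D_n(x').
#
# Forward:  M_n = n! * sum_{k=1}^{n} tau^k/k! * Bhat_{n,k}(D_1, ..., D_{n-k+1})
# Inverse:  D_n = 1/(n! tau) * sum_{k=1}^{n} (-1)^{k-1} (k-1)!
#                                 * B_{n,k}(M_1, ..., M_{n-k+1})
# The inverse is the moment -> cumulant transformation: n! tau D_n is the
# n-th cumulant of the increment distribution at lag tau.

.D_syms <- function(n) lapply(seq_len(n), function(i) km_sym(paste0("D", i)))
.M_syms <- function(n) lapply(seq_len(n), function(i) km_sym(paste0("M", i)))

.new_expansion <- function(n, direction, poly) {
  structure(list(n = n, direction = direction, poly = poly),
            class = "km_expansion")
}

#' Conditional moments as exact polynomials in the KM coefficients
#'
#' Builds the derivative-free finite-time expansion of the n-th conditional
#' moment `M_n(x', tau)` as an exact polynomial in `tau` and `D1...Dn`,
#' via partial ordinary Bell polynomials. Derivative terms of the KM
#' coefficients (see [expand_with_derivatives()]) are excluded, as in the
#' closed-form estimation relations.
#'
#' @param n moment order, positive integer.
#' @return A `km_expansion` with `direction = "moments_in_D"`; element
#'   `$poly` is the exact [km_sym()] polynomial.
#' @examples
#' moments_from_km(2) # 2*tau*D2 + tau^2*D1^2
#' @export
moments_from_km <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 1) {
    stop("n must be a positive integer")
  }
  tau <- km_sym("tau")
  D <- .D_syms(n)
  acc <- km_const(0)
  for (k in seq_len(n)) {
    bk <- ordinary_bell(n, k, D[seq_len(n - k + 1L)])
    acc <- acc + km_const(factorial(n) / factorial(k)) * tau^k * bk
  }
  .new_expansion(n, "moments_in_D", acc)
}

#' KM coefficients as exact polynomials in the conditional moments
#'
#' Builds the reciprocal Bell-polynomial inversion expressing
#' `D_n = P_n(M1, ..., Mn) / (n! * tau)` with
#' `P_n = sum_k (-1)^(k-1) (k-1)! B_{n,k}(M1, ..., M_{n-k+1})`, the
#' moment-to-cumulant polynomial.
#'
#' @param n coefficient order, positive integer.
#' @return A `km_expansion` with `direction = "D_in_moments"`; `$poly` holds
#'   the numerator polynomial `P_n` (equal to `n! * tau * D_n`).
#' @examples
#' render_km(km_from_moments(2)) # "(M2 - M1^2)/(2*tau)"
#' @export
km_from_moments <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 1) {
    stop("n must be a positive integer")
  }
  M <- .M_syms(n)
  acc <- km_const(0)
  for (k in seq_len(n)) {
    bk <- exponential_bell(n, k, M[seq_len(n - k + 1L)])
    acc <- acc + km_const((-1)^(k - 1) * factorial(k - 1)) * bk
  }
  .new_expansion(n, "D_in_moments", acc)
}

# numeric partial ordinary Bell evaluation; inputs is a numeric vector or a
# matrix with one column per slot (bins evaluated in parallel)
.bell_ord_num <- function(n, m, inputs) {
  inputs <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1L)
  acc <- numeric(nrow(inputs))
  for (j in enumerate_partitions(n, m)) {
    v <- rep(factorial(m) / prod(factorial(j)), nrow(inputs))
    for (r in seq_along(j)) if (j[r] > 0) v <- v * inputs[, r]^j[r]
    acc <- acc + v
  }
  acc
}

#' Numeric finite-time inversion of conditional moments
#'
#' Recovers `D_1, ..., D_n` from observed conditional moments
#' `M_1, ..., M_n` at lag `tau` by recursively solving the forward Bell
#' expansion truncated at `tau^order_m`:
#' `order_m = 1` gives the uncorrected estimator `M_n/(n! tau)`;
#' `order_m = 2` additionally subtracts the `Bhat_{n,2}` group; the full
#' order (`order_m >= n`) is the exact reciprocal inversion.
#'
#' @param moment_values numeric vector `(M_1, ..., M_n)`, or a matrix with
#'   `n` columns (rows inverted independently, e.g. one row per state bin).
#' @param tau positive lag time.
#' @param order_m truncation order of the correction, `>= 1`; capped at `n`
#'   per coefficient. Use `Inf` (default) for the full-order inversion.
#' @return numeric vector (or matrix) of `D_1, ..., D_n`. Non-finite input
#'   moments propagate to non-finite coefficients.
#' @examples
#' M <- km_forward_eval(c(1, 0.3, 0, 0), tau = 0.1)
#' invert_numeric(M, tau = 0.1) # recovers 1, 0.3, 0, 0
#' @export
invert_numeric <- function(moment_values, tau, order_m = Inf) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a positive number")
  }
  if (length(order_m) != 1L || order_m < 1) stop("order_m must be >= 1")
  M <- if (is.matrix(moment_values)) moment_values else matrix(moment_values, nrow = 1L)
  n_max <- ncol(M)
  D <- matrix(NA_real_, nrow(M), n_max)
  for (n in seq_len(n_max)) {
    kmax <- min(n, order_m)
    corr <- 0
    if (kmax >= 2) for (k in 2:kmax) {
      bk <- .bell_ord_num(n, k, D[, seq_len(n - k + 1L), drop = FALSE])
      corr <- corr + factorial(n) / factorial(k) * tau^k * bk
    }
    D[, n] <- (M[, n] - corr) / (factorial(n) * tau)
  }
  if (is.matrix(moment_values)) D else drop(D)
}

#' Evaluate the forward moment expansion numerically
#'
#' Computes `M_1, ..., M_n` exactly from given KM coefficient values via the
#' derivative-free Bell expansion; the numeric counterpart (and inverse) of
#' [invert_numeric()].
#'
#' @param D_values numeric vector `(D_1, ..., D_n)` or matrix with `n` columns.
#' @param tau positive lag time.
#' @param order_m truncation order of the forward series (default full).
#' @return numeric vector (or matrix) of conditional moments.
#' @export
km_forward_eval <- function(D_values, tau, order_m = Inf) {
  D <- if (is.matrix(D_values)) D_values else matrix(D_values, nrow = 1L)
  n_max <- ncol(D)
  M <- matrix(NA_real_, nrow(D), n_max)
  for (n in seq_len(n_max)) {
    acc <- 0
    for (k in seq_len(min(n, order_m))) {
      bk <- .bell_ord_num(n, k, D[, seq_len(n - k + 1L), drop = FALSE])
      acc <- acc + factorial(n) / factorial(k) * tau^k * bk
    }
    M[, n] <- acc
  }
  if (is.matrix(D_values)) M else drop(M)
}

#' Render an expansion or polynomial as text
#'
#' Produces a deterministic canonical string, either plain (parseable back
#' with [parse_km()]) or LaTeX. Terms are ordered by increasing power of
#' `tau`, then lexicographically on symbol indices.
#'
#' @param x a `km_expansion`, `km_poly`, or list of operator terms from
#'   [expand_with_derivatives()].
#' @param format `"plain"` or `"latex"`.
#' @return character scalar.
#' @examples
#' render_km(moments_from_km(1)) # "tau*D1"
#' @export
render_km <- function(x, format = c("plain", "latex")) {
  format <- match.arg(format)
  if (inherits(x, "km_operator_terms")) return(.render_operator(x, format))
  if (inherits(x, "km_expansion")) {
    if (x$direction == "moments_in_D") {
      return(if (format == "plain") .poly_plain(x$poly) else .poly_latex(x$poly))
    }
    nf <- factorial(x$n)
    body <- if (format == "plain") .poly_plain(x$poly) else .poly_latex(x$poly)
    if (format == "plain") {
      if (length(x$poly$terms) > 1L) body <- paste0("(", body, ")")
      if (nf == 1) return(paste0(body, "/tau"))
      return(paste0(body, "/(", format(nf, scientific = FALSE), "*tau)"))
    }
    denom <- if (nf == 1) "\\tau" else paste0(format(nf, scientific = FALSE), "\\tau")
    return(paste0("\\frac{", body, "}{", denom, "}"))
  }
  if (inherits(x, "km_poly")) {
    return(if (format == "plain") .poly_plain(x) else .poly_latex(x))
  }
  stop("cannot render object of class ", paste(class(x), collapse = "/"))
}

#' @export
print.km_expansion <- function(x, ...) {
  cat(sprintf("%s expansion, order n = %d:\n",
              if (x$direction == "moments_in_D") "M_n(D)" else "D_n(M)", x$n))
  cat(render_km(x), "\n")
  invisible(x)
}

.parse_term <- function(txt) {
  neg <- FALSE
  if (startsWith(txt, "-")) { neg <- TRUE; txt <- substring(txt, 2L) }
  facs <- strsplit(txt, "*", fixed = TRUE)[[1]]
  num <- 1; den <- 1
  pow <- stats::setNames(numeric(0), character(0))
  for (f in facs) {
    if (grepl("^[0-9]+(/[0-9]+)?$", f)) {
      parts <- strsplit(f, "/", fixed = TRUE)[[1]]
      num <- num * as.numeric(parts[1])
      if (length(parts) == 2L) den <- den * as.numeric(parts[2])
    } else if (grepl("^[A-Za-z][A-Za-z0-9]*(\\^[0-9]+)?$", f)) {
      parts <- strsplit(f, "^", fixed = TRUE)[[1]]
      e <- if (length(parts) == 2L) as.numeric(parts[2]) else 1
      pow[parts[1]] <- (if (parts[1] %in% names(pow)) pow[[parts[1]]] else 0) + e
    } else {
      stop("cannot parse factor: '", f, "'")
    }
  }
  if (neg) num <- -num
  .km_term(num, den, pow)
}

#' Parse a plain-format polynomial string
#'
#' Inverse of [render_km()] on the `"plain"` format: accepts bare
#' polynomials ("2*tau*D2 + tau^2*D1^2") and the quotient form emitted for
#' inverse expansions ("(M2 - M1^2)/(2*tau)"), returning an exact `km_poly`
#' (quotients are cleared by multiplying through by the denominator, so
#' parsing an inverse expansion returns its numerator polynomial `n! tau D_n`).
#'
#' @param text character scalar in canonical plain format.
#' @return A `km_poly`.
#' @export
parse_km <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^\\((.*)\\)/\\(([0-9]+\\*)?tau\\)$", txt))[[1]]
  if (!length(m)) {
    m <- regmatches(txt, regexec("^([^()]*)/\\(([0-9]+\\*)?tau\\)$", txt))[[1]]
  }
  if (!length(m)) {
    m <- regmatches(txt, regexec("^([^()/]*)/tau$", txt))[[1]]
  }
  if (length(m)) txt <- m[2] # numerator only; denominator is n!*tau by construction
  txt <- gsub(" - ", " + -", txt, fixed = TRUE)
  pieces <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) stop("empty expression")
  .km_normalize(lapply(pieces, .parse_term))
}

#' Cumulants from raw moments by the classical recursion
#'
#' Reference implementation of the moment-to-cumulant recursion
#' `k_n = mu'_n - sum_{j=1}^{n-1} choose(n-1, j-1) k_j mu'_{n-j}`,
#' used as an independent cross-check of the reciprocal Bell inversion
#' (for which `n! tau D_n` evaluated at `M_k = mu'_k` must equal `k_n`).
#'
#' @param moments numeric vector of raw moments `mu'_1, ..., mu'_n`.
#' @return numeric vector of cumulants `k_1, ..., k_n`.
#' @export
cumulants_from_moments <- function(moments) {
  n <- length(moments)
  kap <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    if (i > 1) for (j in seq_len(i - 1)) {
      s <- s + choose(i - 1, j - 1) * kap[j] * moments[i - j]
    }
    kap[i] <- moments[i] - s
  }
  kap
}
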