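# Independent oracles and small utilities shared across the test files.

# Brute-force enumeration of the Bell-constraint solutions: all count vectors
# (j_1, ..., j_{n-m+1}) with sum(j) = m and sum(r j_r) = n, by exhaustive
# grid search. Deliberately naive; the package's recursive enumerator is
# checked against this.
bf_partitions <- function(n, m) {
  len <- n - m + 1L
  ranges <- lapply(seq_len(len), function(r) 0:min(m, n %/% r))
  grid <- as.matrix(do.call(expand.grid, ranges))
  keep <- rowSums(grid) == m & as.vector(grid %*% seq_len(len)) == n
  sol <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(sol)), function(i) unname(sol[i, ]))
}

# canonical string for a partition count vector, for set comparisons
pkey <- function(j) paste(j, collapse = ",")

# canonical multiset key of an operator term (coefficient + factors)
term_key <- function(t) {
  fac <- t$factors
  o <- order(fac[, 1], fac[, 2])
  paste0(t$num, "/", t$den, "|tau^", t$tau_power, "|",
         paste(fac[o, 1], fac[o, 2], sep = "'", collapse = ","))
}

# operator-term lists as multisets
expect_same_terms <- function(a, b) {
  expect_setequal(vapply(unclass(a), term_key, character(1)),
                  vapply(unclass(b), term_key, character(1)))
}

# build a km_operator_terms-like list from a plain spec: list of
# list(num, den, factors = rbind(c(p, d), ...)) at a common tau power
make_terms <- function(n, tau_power, specs) {
  terms <- lapply(specs, function(s) {
    fac <- s$factors
    fac <- fac[order(fac[, 1], fac[, 2]), , drop = FALSE]
    list(num = s$num, den = s$den, tau_power = tau_power, factors = fac)
  })
  structure(terms, class = "km_operator_terms", truncated = FALSE, n = n,
            order = tau_power, truncation_N = 2L, max_deriv = Inf)
}

# exact polynomial from a plain canonical string
P <- function(s) parse_km(s)

# moments of a small discrete distribution (values v, probabilities p)
discrete_moments <- function(v, p, n_max) {
  vapply(seq_len(n_max), function(n) sum(p * v^n), numeric(1))
}

# weighted average of a coefficient column over the default central range
dbar <- function(estimate, fit_range = NULL) {
  km_average(estimate, fit_range)
}
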