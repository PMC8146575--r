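# Exact forward/inverse relations between conditional moments and KM
# coefficients.

# the full printed moment list and cumulant-style inversions, expanded to
# individual monomials in canonical form
moment_strings <- c(
  "tau*D1",
  "2*tau*D2 + tau^2*D1^2",
  "6*tau*D3 + 6*tau^2*D1*D2 + tau^3*D1^3",
  "24*tau*D4 + 24*tau^2*D1*D3 + 12*tau^2*D2^2 + 12*tau^3*D1^2*D2 + tau^4*D1^4",
  paste("120*tau*D5 + 120*tau^2*D1*D4 + 120*tau^2*D2*D3 + 60*tau^3*D1^2*D3",
        "+ 60*tau^3*D1*D2^2 + 20*tau^4*D1^3*D2 + tau^5*D1^5"),
  paste("720*tau*D6 + 720*tau^2*D1*D5 + 720*tau^2*D2*D4 + 360*tau^2*D3^2",
        "+ 360*tau^3*D1^2*D4 + 720*tau^3*D1*D2*D3 + 120*tau^3*D2^3",
        "+ 120*tau^4*D1^3*D3 + 180*tau^4*D1^2*D2^2 + 30*tau^5*D1^4*D2",
        "+ tau^6*D1^6"))

inversion_strings <- c(
  "M1",
  "M2 - M1^2",
  "M3 - 3*M1*M2 + 2*M1^3",
  "M4 - 4*M1*M3 - 3*M2^2 + 12*M1^2*M2 - 6*M1^4",
  paste("M5 - 5*M1*M4 - 10*M2*M3 + 20*M1^2*M3 + 30*M1*M2^2 - 60*M1^3*M2",
        "+ 24*M1^5"),
  paste("M6 - 6*M1*M5 - 15*M2*M4 - 10*M3^2 + 30*M1^2*M4 + 120*M1*M2*M3",
        "+ 30*M2^3 - 120*M1^3*M3 - 270*M1^2*M2^2 + 360*M1^4*M2 - 120*M1^6"))

test_that("forward moment expansion reproduces the n <= 6 closed forms term-for-term", {
  for (n in 1:6) {
    expect_true(km_poly_equal(moments_from_km(n)$poly, P(moment_strings[n])),
                label = sprintf("M%d expansion", n))
  }
  expect_error(moments_from_km(0), "positive")
})

test_that("reciprocal inversion reproduces the n <= 6 cumulant polynomials term-for-term", {
  for (n in 1:6) {
    expect_true(km_poly_equal(km_from_moments(n)$poly, P(inversion_strings[n])),
                label = sprintf("D%d inversion", n))
  }
  expect_error(km_from_moments(-2), "positive")
})

test_that("forward-then-inverse substitution is the symbolic identity up to n = 8", {
  fw <- lapply(1:8, function(k) moments_from_km(k)$poly)
  names(fw) <- paste0("M", 1:8)
  for (n in 1:8) {
    res <- km_substitute(km_from_moments(n)$poly, fw)
    target <- km_const(factorial(n)) * km_sym("tau") * km_sym(paste0("D", n))
    expect_true(km_poly_equal(res, target), label = sprintf("round trip n=%d", n))
  }
})

test_that("expansion monomials carry the exact index grading", {
  for (n in 1:8) {
    for (t in moments_from_km(n)$poly$terms) {
      dsy <- t$pow[startsWith(names(t$pow), "D")]
      idx <- as.integer(sub("D", "", names(dsy)))
      expect_equal(sum(idx * dsy), n)
      expect_true(t$pow[["tau"]] >= 1 && t$pow[["tau"]] <= n)
    }
    for (t in km_from_moments(n)$poly$terms) {
      msy <- t$pow[startsWith(names(t$pow), "M")]
      idx <- as.integer(sub("M", "", names(msy)))
      expect_equal(sum(idx * msy), n)
    }
  }
})

test_that("numeric inversion recovers exact forward moments to machine precision", {
  set.seed(5)
  for (rep in 1:5) {
    D <- round(runif(6, -2, 2), 3)
    tau <- runif(1, 0.01, 0.5)
    M <- km_forward_eval(D, tau)
    expect_equal(invert_numeric(M, tau), D, tolerance = 1e-10)
  }
  # matrix form, one row per bin
  D <- matrix(round(runif(12, -1, 1), 3), 2, 6)
  M <- km_forward_eval(D, 0.05)
  expect_equal(invert_numeric(M, 0.05), D, tolerance = 1e-10)
  expect_error(invert_numeric(c(0.1, 0.2), tau = -1), "positive")
  expect_error(invert_numeric(c(0.1, 0.2), tau = 0.1, order_m = 0), "order_m")
})

test_that("odd-moment-free input makes D2 exact at every order", {
  d <- 0.37
  tau <- 0.2
  M <- c(0, 2 * tau * d, 0, 24 * tau * 0 + 12 * tau^2 * d^2)
  for (ord in c(1, 2, 3, Inf)) {
    D <- invert_numeric(M, tau, order_m = ord)
    if (ord >= 2) expect_equal(D[2], d) else expect_equal(D[2], M[2] / (2 * tau))
  }
})

test_that("truncated inversion reproduces the approximation hierarchy", {
  set.seed(9)
  D <- round(runif(6, -1, 1), 3)
  tau <- 0.1
  M <- km_forward_eval(D, tau)
  # order 1 is the naive estimator
  expect_equal(invert_numeric(M, tau, order_m = 1),
               M / (factorial(1:6) * tau))
  # order 2 subtracts exactly the Bhat_{n,2} group of the order-2 estimates
  D2est <- invert_numeric(M, tau, order_m = 2)
  for (n in 2:6) {
    b2 <- ordinary_bell(n, 2, D2est[seq_len(n - 1)])
    expect_equal(D2est[n],
                 (M[n] - factorial(n) / 2 * tau^2 * b2) / (factorial(n) * tau))
  }
  # the hierarchy converges: full order is exact, and for D2 order 2 already is
  expect_equal(invert_numeric(M, tau, order_m = 2)[2], D[2])
  expect_equal(invert_numeric(M, tau, order_m = Inf), D, tolerance = 1e-12)
})

test_that("first- and full-order estimates coincide as tau -> 0 on OU closed-form moments", {
  a <- 1; b <- 0.5; x0 <- 0.8
  gap_at <- function(tau) {
    M <- ou_conditional_moments(x0, a, b, tau)
    # D1 has no correction; the D2 correction subtracts the M1^2 group,
    # which is O(tau^2) in the moment expansion, so the estimator gap
    # M1^2/(2 tau) vanishes linearly in tau
    abs(M[["M2"]] / (2 * tau) - invert_numeric(M, tau)[2])
  }
  taus <- c(0.2, 0.1, 0.05)
  gap <- vapply(taus, gap_at, numeric(1))
  expect_equal(gap[1],
               ou_conditional_moments(x0, a, b, 0.2)[["M1"]]^2 / (2 * 0.2))
  expect_lt(gap[2] / gap[1], 0.65)
  expect_lt(gap[3] / gap[2], 0.65)
})

test_that("the inversion is the moment-to-cumulant map (recursion cross-check)", {
  mom <- discrete_moments(c(0, 1, 3), c(0.2, 0.5, 0.3), 8)
  kap <- cumulants_from_moments(mom)
  for (n in 1:8) {
    vals <- as.list(mom[seq_len(n)])
    names(vals) <- paste0("M", seq_len(n))
    expect_equal(km_eval(km_from_moments(n)$poly, vals), kap[n],
                 tolerance = 1e-8)
  }
})

test_that("rendering is canonical and parse inverts it", {
  expect_identical(render_km(moments_from_km(1)), "tau*D1")
  expect_identical(render_km(moments_from_km(2)), "2*tau*D2 + tau^2*D1^2")
  expect_identical(render_km(km_from_moments(1)), "M1/tau")
  expect_identical(render_km(km_from_moments(2)), "(M2 - M1^2)/(2*tau)")
  for (n in 1:6) {
    fw <- moments_from_km(n)
    expect_true(km_poly_equal(parse_km(render_km(fw)), fw$poly))
    inv <- km_from_moments(n)
    expect_true(km_poly_equal(parse_km(render_km(inv)), inv$poly))
    # render of parse is the identity on the plain format
    expect_identical(render_km(parse_km(render_km(fw))), render_km(fw))
  }
  expect_match(render_km(moments_from_km(2), format = "latex"), "\\\\tau")
})
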