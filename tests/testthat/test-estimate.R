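# Non-parametric conditional moments and corrected coefficient estimation.

test_that("a constant series yields zero moments in a single occupied bin", {
  cm <- conditional_moments(rep(2.5, 500), n_max = 4, dt = 0.1, min_count = 10)
  occ <- cm$counts > 0
  expect_identical(sum(occ), 1L)
  expect_equal(unname(cm$moments[occ, ]), rep(0, 4))
})

test_that("bin partition covers the range with half-open intervals", {
  x <- seq(-1, 1, length.out = 1000)
  cm <- conditional_moments(x, n_max = 1, dt = 1, bins = 10,
                            range = c(-1, 1), min_count = 1)
  # every state sample except those outside [lo, hi) lands in exactly one bin
  expect_identical(sum(cm$counts), sum(x[-length(x)] >= -1 & x[-length(x)] < 1))
  # boundary values: a state equal to an inner edge belongs to the upper bin
  cm2 <- conditional_moments(c(0, 0.5, 0), n_max = 1, dt = 1, bins = 2,
                             range = c(0, 1), min_count = 1)
  expect_identical(cm2$counts, c(1L, 1L))
})

test_that("per-bin M1 tracks the OU closed form within Monte-Carlo error", {
  ts <- simulate_jd(jd_spec(a = 1, b = 0.5, lambda = 0, s = 0, dt = 0.05),
                    4e5, seed = 31)
  cm <- conditional_moments(ts, n_max = 2)
  sel <- !cm$excluded & abs(cm$bin_centers) < 2 * sd(ts$values)
  oracle <- ou_conditional_moments(cm$bin_centers[sel], 1, 0.5, cm$tau)
  # per-bin MC standard error of the mean increment
  v <- 0.25 * (1 - exp(-2 * 0.05)) / 2
  se <- sqrt(v / cm$counts[sel])
  expect_true(all(abs(cm$moments[sel, 1] - oracle[, "M1"]) < 5 * se))
  expect_lt(mean(abs(cm$moments[sel, 2] - oracle[, "M2"])), 5 * v / sqrt(min(cm$counts[sel])))
})

test_that("jump-only series has per-bin M2 near s*lambda*tau", {
  # a = b = 0: increments are pure compound Poisson
  ts <- simulate_jd(jd_spec(a = 0, b = 0, lambda = 0.6, s = 0.75, dt = 0.05),
                    3e5, seed = 41)
  cm <- conditional_moments(ts, n_max = 2)
  sel <- !cm$excluded
  target <- 0.75 * 0.6 * cm$tau
  pooled <- sum(cm$moments[sel, 2] * cm$counts[sel]) / sum(cm$counts[sel])
  expect_lt(abs(pooled - target) / target, 0.1)
})

test_that("estimator is consistent: error shrinks as the series grows", {
  err_at <- function(n_steps) {
    errs <- vapply(1:3, function(k) {
      # integrate finer and down-sample so the integrator bias sits well
      # below the statistical error and the exact OU transition oracle applies
      ts <- simulate_jd(jd_spec(a = 1, b = 0.5, lambda = 0, s = 0, dt = 0.05),
                        n_steps, seed = 100 + k, refine = 10)
      cm <- conditional_moments(ts, n_max = 2, range = c(-1.4, 1.4))
      sel <- !cm$excluded
      # evaluate the oracle at the occupancy-weighted mean state of each
      # bin, so the comparison is free of within-bin discretisation bias
      oracle <- ou_conditional_moments(cm$state_mean[sel], 1, 0.5, cm$tau)
      mean(abs(cm$moments[sel, 1] - oracle[, "M1"]))
    }, numeric(1))
    mean(errs)
  }
  e1 <- err_at(2e4)
  e2 <- err_at(8e4)
  # quadrupling the length should halve the error, within noise
  expect_lt(e2 / e1, 0.75)
})

test_that("kernel estimator agrees with the histogram on smooth data", {
  ts <- simulate_jd(jd_spec(a = 1, b = 0.5, lambda = 0, s = 0, dt = 0.05),
                    1e5, seed = 51)
  ch <- conditional_moments(ts, n_max = 2)
  ck <- conditional_moments(ts, n_max = 2, estimator = "kernel")
  expect_identical(ck$estimator_kind, "kernel")
  sel <- !ch$excluded & !ck$excluded
  expect_lt(mean(abs(ch$moments[sel, 1] - ck$moments[sel, 1])), 5e-3)
})

test_that("bin-wise inversion: symmetric bins, round trips, and D1 across orders", {
  # symmetric bin with vanishing odd moments: D2 = M2/(2 tau) at every order
  tau <- 0.1
  M <- matrix(c(0, 2 * tau * 0.4, 0, 12 * tau^2 * 0.4^2), 1, 4)
  for (ord in list(2, 4, "full")) {
    cmock <- structure(list(bin_edges = c(-1, 1), bin_centers = 0, counts = 1000L,
                            excluded = FALSE, tau = tau, dt = tau, lag = 1L,
                            n_max = 4L, estimator_kind = "histogram",
                            min_count = 100L, bandwidth = NA_real_,
                            moments = M), class = "km_moments")
    est <- km_coefficients(cmock, order_m = ord)
    expect_equal(unname(est$D[1, 2]), 0.4)
  }
  # exact polynomial moments from chosen D round-trip at full order
  D <- matrix(c(-0.5, 0.35, 0.01, 0.042, 0.001, 0.0053), 1, 6)
  Mx <- km_forward_eval(D, tau)
  cmock <- structure(list(bin_edges = c(-1, 1), bin_centers = 0, counts = 1000L,
                          excluded = FALSE, tau = tau, dt = tau, lag = 1L,
                          n_max = 6L, estimator_kind = "histogram",
                          min_count = 100L, bandwidth = NA_real_,
                          moments = Mx), class = "km_moments")
  est <- km_coefficients(cmock, order_m = "full")
  expect_equal(unname(est$D[1, ]), c(D), tolerance = 1e-12)
  # D1 identical at every order on real data
  ts <- simulate_jd(jd_spec(a = 1, b = 0.5, dt = 0.1), 5e4, seed = 61)
  cm <- conditional_moments(ts, n_max = 6)
  e1 <- suppressWarnings(km_coefficients(cm, order_m = 1))
  ef <- suppressWarnings(km_coefficients(cm, order_m = "full"))
  expect_identical(e1$D[, 1], ef$D[, 1])
  # for D2 the order-2 and the full-order corrections are identical
  e2 <- suppressWarnings(km_coefficients(cm, order_m = 2))
  expect_equal(e2$D[, 2], ef$D[, 2])
  expect_error(km_coefficients(cm, order_m = 7), "n_max")
})

test_that("negative corrected D2/D4 from noise is flagged, not clipped", {
  tau <- 0.1
  M <- matrix(c(0.5, 0.2, 0, 0), 1, 4) # M2 < M1^2: corrected D2 negative
  cmock <- structure(list(bin_edges = c(-1, 1), bin_centers = 0, counts = 500L,
                          excluded = FALSE, tau = tau, dt = tau, lag = 1L,
                          n_max = 4L, estimator_kind = "histogram",
                          min_count = 100L, bandwidth = NA_real_,
                          moments = M), class = "km_moments")
  expect_warning(est <- km_coefficients(cmock, order_m = "full"), "negative")
  expect_lt(est$D[1, 2], 0)
  expect_true(est$negative_flag[1])
})

test_that("tables round-trip byte-identically with exclusion flags intact", {
  ts <- simulate_jd(jd_spec(a = 1, b = 0.5, dt = 0.1), 2e4, seed = 71)
  cm <- conditional_moments(ts, n_max = 4, min_count = 200)
  expect_gt(sum(cm$excluded), 0) # sparse outer bins present
  f1 <- tempfile(); f2 <- tempfile()
  write_km_table(cm, f1)
  back <- read_km_table(f1)
  write_km_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(back$excluded, cm$excluded)
  expect_equal(back$moments, cm$moments, ignore_attr = TRUE)
  expect_equal(back$tau, cm$tau)
  header <- readLines(f1)
  expect_true(any(grepl("^# estimator_kind=histogram$", header)))
  expect_true(any(grepl("^# bins=30$", header)))
  # coefficient tables round-trip too, keeping order_m
  est <- suppressWarnings(km_coefficients(cm, order_m = "full"))
  f3 <- tempfile(); f4 <- tempfile()
  write_km_table(est, f3)
  est_back <- read_km_table(f3)
  write_km_table(est_back, f4)
  expect_identical(readLines(f3), readLines(f4))
  expect_identical(est_back$order_m, "full")
  expect_equal(est_back$D, est$D, ignore_attr = TRUE)
})

test_that("degenerate inputs raise clear errors", {
  expect_error(conditional_moments(numeric(0), dt = 0.1), "at least 2")
  expect_error(conditional_moments(c(1, 2, 3), dt = 0.1, lag = 5), "lag")
  expect_error(conditional_moments(c(1, 2, 3)), "dt")
  expect_error(conditional_moments(c(1, 2, 3), dt = 0.1, n_max = 0), "n_max")
})
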