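# Euler-Maruyama integration of the jump-diffusion SDE
#   dX_t = a(X_t) dt + b(X_t) dW(t) + xi dJ(t),
# with J a Poisson process of rate lambda and xi ~ N(0, s) i.i.d. amplitudes.
# The default drift is linear mean-reverting, a(x) = -a * x.

#' Jump-diffusion process specification
#'
#' Parameters of the mean-reverting jump-diffusion
#' `dX = -a X dt + b dW + xi dJ`: with `lambda = s = 0` this is the
#' Ornstein-Uhlenbeck process. `drift` and `diffusion` may alternatively be
#' functions of the state for non-linear variants.
#'
#' @param a mean-reverting strength (`> 0` for a stationary process); used
#'   when `drift` is `NULL`.
#' @param b constant diffusion amplitude (`>= 0`); used when `diffusion` is
#'   `NULL`.
#' @param lambda Poisson jump rate per unit time, `>= 0`.
#' @param s variance of the zero-mean Gaussian jump amplitude, `>= 0`.
#' @param dt sampling (and default integration) time step, `> 0`.
#' @param x0 initial state.
#' @param drift optional function `f(x)` replacing the linear drift `-a*x`.
#' @param diffusion optional function `g(x)` replacing the constant `b`.
#' @return An object of class `jd_spec`.
#' @examples
#' jd_spec(a = 1, b = 0.5, dt = 0.1)                 # Ornstein-Uhlenbeck
#' jd_spec(a = 0.5, b = 0.5, lambda = 0.6, s = 0.75) # jump-diffusion
#' @export
jd_spec <- function(a = 1, b = 0.5, lambda = 0, s = 0, dt = 0.1, x0 = 0,
                    drift = NULL, diffusion = NULL) {
  if (!is.null(drift) && !is.function(drift)) stop("drift must be a function")
  if (!is.null(diffusion) && !is.function(diffusion)) stop("diffusion must be a function")
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(dt) || dt <= 0) stop("dt must be a positive number")
  if (!num_ok(lambda) || lambda < 0) stop("lambda must be non-negative")
  if (!num_ok(s) || s < 0) stop("s must be non-negative")
  if (is.null(diffusion) && (!num_ok(b) || b < 0)) stop("b must be non-negative")
  if (is.null(drift) && !num_ok(a)) stop("a must be a number")
  if (!num_ok(x0)) stop("x0 must be a number")
  structure(list(a = a, b = b, lambda = lambda, s = s, dt = dt, x0 = x0,
                 drift = drift, diffusion = diffusion),
            class = "jd_spec")
}

#' @export
print.jd_spec <- function(x, ...) {
  cat("jump-diffusion specification\n")
  cat(sprintf("  drift:     %s\n",
              if (is.null(x$drift)) sprintf("-%g * x", x$a) else "<function>"))
  cat(sprintf("  diffusion: %s\n",
              if (is.null(x$diffusion)) sprintf("%g", x$b) else "<function>"))
  cat(sprintf("  jumps:     lambda = %g, amplitude variance s = %g\n",
              x$lambda, x$s))
  cat(sprintf("  dt = %g, x0 = %g\n", x$dt, x$x0))
  invisible(x)
}

#' Simulate a jump-diffusion trajectory
#'
#' Euler-Maruyama scheme
#' `X_{k+1} = X_k + a(X_k) dt + b(X_k) sqrt(dt) G_k + S_k`, where `G_k` are
#' standard normal and `S_k` is the compound-Poisson increment: with
#' `K_k ~ Poisson(lambda dt)` jumps in a step, the sum of `K_k` independent
#' `N(0, s)` amplitudes is drawn exactly as `sqrt(K_k s) Z_k`,
#' `Z_k ~ N(0,1)`. All random draws happen in a fixed block order (Gaussian
#' increments, jump counts, jump amplitudes), so a trajectory is fully
#' reproducible from `seed` irrespective of how many jumps occur.
#'
#' @param spec a [jd_spec()].
#' @param n_steps number of sampled increments; the returned series has
#'   `n_steps + 1` values starting at `x0`.
#' @param seed integer random seed.
#' @param refine integer `>= 1`; integrate with the finer internal step
#'   `dt/refine` and down-sample back to `dt`.
#' @return An object of class `km_series`: list with `values`, `dt`, and
#'   `meta` (spec, seed, refine, jump count).
#' @examples
#' ts <- simulate_jd(jd_spec(a = 1, b = 0.5, dt = 0.1), n_steps = 1000, seed = 1)
#' @export
simulate_jd <- function(spec, n_steps, seed = 1L, refine = 1L) {
  stopifnot(inherits(spec, "jd_spec"))
  if (length(n_steps) != 1L || !is.finite(n_steps) || n_steps < 1 ||
      n_steps != round(n_steps)) {
    stop("n_steps must be a positive integer")
  }
  if (refine < 1 || refine != round(refine)) stop("refine must be a positive integer")
  n_int <- n_steps * refine
  dt_i <- spec$dt / refine
  set.seed(as.integer(seed))
  G <- stats::rnorm(n_int)
  K <- if (spec$lambda > 0) stats::rpois(n_int, spec$lambda * dt_i) else integer(n_int)
  Z <- stats::rnorm(n_int)
  jumps <- sqrt(K * spec$s) * Z
  linear <- is.null(spec$drift) && is.null(spec$diffusion)
  if (linear) {
    w <- spec$b * sqrt(dt_i) * G + jumps
    x <- stats::filter(w, 1 - spec$a * dt_i, method = "recursive",
                       init = spec$x0)
    x <- c(spec$x0, as.numeric(x))
  } else {
    fdrift <- if (is.null(spec$drift)) function(x) -spec$a * x else spec$drift
    fdiff <- if (is.null(spec$diffusion)) function(x) spec$b else spec$diffusion
    x <- numeric(n_int + 1L)
    x[1] <- spec$x0
    sq <- sqrt(dt_i)
    for (k in seq_len(n_int)) {
      x[k + 1L] <- x[k] + fdrift(x[k]) * dt_i + fdiff(x[k]) * sq * G[k] + jumps[k]
    }
  }
  if (refine > 1L) x <- x[seq(1L, n_int + 1L, by = refine)]
  structure(list(values = x, dt = spec$dt,
                 meta = list(spec = spec, seed = as.integer(seed),
                             refine = as.integer(refine),
                             n_jumps = sum(K))),
            class = "km_series")
}

#' @export
print.km_series <- function(x, ...) {
  cat(sprintf("time series: %d values, dt = %g (T = %g)\n",
              length(x$values), x$dt, (length(x$values) - 1) * x$dt))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed = %d\n", x$meta$seed))
  invisible(x)
}

#' Exact conditional moments of the Ornstein-Uhlenbeck transition
#'
#' Closed-form conditional moments of the increment `X(t+tau) - x0` for the
#' OU process `dX = -a X dt + b dW`, whose transition law is Gaussian with
#' mean `x0 exp(-a tau)` and variance `v = b^2 (1 - exp(-2 a tau))/(2a)`:
#' `M1 = x0 (exp(-a tau) - 1)`, `M2 = M1^2 + v`, `M3 = M1^3 + 3 M1 v`,
#' `M4 = M1^4 + 6 M1^2 v + 3 v^2`. Serves as an independent oracle for the
#' non-parametric estimators.
#'
#' @param x0 conditioning state.
#' @param a mean-reverting strength, `> 0`.
#' @param b diffusion amplitude.
#' @param tau lag time, `> 0`.
#' @return named numeric vector `(M1, M2, M3, M4)`; vectorised over `x0`.
#' @export
ou_conditional_moments <- function(x0, a, b, tau) {
  if (!is.numeric(a) || a <= 0) stop("a must be positive")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  M1 <- x0 * (exp(-a * tau) - 1)
  v <- b^2 * (1 - exp(-2 * a * tau)) / (2 * a)
  out <- cbind(M1 = M1,
               M2 = M1^2 + v,
               M3 = M1^3 + 3 * M1 * v,
               M4 = M1^4 + 6 * M1^2 * v + 3 * v^2)
  if (length(x0) == 1L) out[1, ] else out
}

#' Write a time series to a plain-text file
#'
#' Format: header lines `# dt=<value>` and `# seed=<int>` followed by one
#' value per line in full double precision; [read_series()] restores the
#' series bit-for-bit.
#'
#' @param series a `km_series` (or list with `values`, `dt`, optional
#'   `meta$seed`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  seed <- series$meta$seed
  header <- c(sprintf("# dt=%.17g", series$dt),
              if (!is.null(seed)) sprintf("# seed=%d", seed))
  writeLines(c(header, sprintf("%.17g", series$values)), path)
  invisible(path)
}

#' Read a time series written by [write_series()]
#'
#' @param path input file path.
#' @return A `km_series`.
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  kv <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$dt)) stop("series file is missing the '# dt=' header line")
  dt <- as.numeric(kv$dt)
  if (!is.finite(dt) || dt <= 0) stop("invalid dt in series header: ", kv$dt)
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("cannot parse value at line ", which(!is_header)[bad], ": '",
         body[bad], "'")
  }
  if (length(vals) < 2L) stop("series must contain at least 2 values")
  seed <- if (!is.null(kv$seed)) as.integer(kv$seed) else NULL
  structure(list(values = vals, dt = dt, meta = list(seed = seed)),
            class = "km_series")
}
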