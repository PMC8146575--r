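#' Fit a finite-time corrected Kramers-Moyal model to a time series
#'
#' The main entry point: estimates per-bin conditional moments at lag
#' `lag * dt`, inverts them to KM coefficients both uncorrected
#' (`order 1`, the naive `M_n/(n! tau)`) and at full finite-time correction,
#' recovers the drift slope, classifies the dynamics as diffusion or
#' jump-diffusion by comparing the corrected `Dbar4` with its batch-means
#' standard error, and -- when jumps are detected -- recovers the jump rate
#' and amplitude variance from the `D2`, `D4`, `D6` ratios.
#'
#' @param series a `km_series` (from [simulate_jd()] or [read_series()]) or
#'   numeric vector.
#' @param dt sampling interval, required for a bare numeric vector.
#' @param n_max highest moment/coefficient order (default 6; at least 6 is
#'   required for jump recovery).
#' @param lag integer lag in samples (default 1, the smallest available
#'   temporal difference).
#' @param bins,range,min_count,estimator,bandwidth binning configuration
#'   passed to [conditional_moments()].
#' @param fit_range central state interval for drift fitting, coefficient
#'   averaging and classification; default mean +/- 2 sd.
#' @param classify_factor detection threshold in standard errors (default 3).
#' @param n_batches batches for the standard errors (default 20).
#' @return An object of class `kmfit` with components `moments`
#'   (`km_moments`), `naive` and `corrected` (`km_estimate` at order 1 and
#'   full order), `drift` (linear drift fit), `classification`, `params`
#'   (`km_jump_params`, jump entries `NA` for diffusive data), `se`
#'   (batch-means standard errors of the averaged coefficients), `dt`,
#'   `fit_range`. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `simulate`.
#' @examples
#' ts <- simulate_jd(jd_spec(a = 1, b = 0.5, lambda = 0, s = 0, dt = 0.05),
#'                   n_steps = 2e4, seed = 7)
#' fit <- kmfit(ts)
#' coef(fit)
#' @export
kmfit <- function(series, dt = NULL, n_max = 6L, lag = 1L, bins = 30L,
                  range = NULL, min_count = 100L,
                  estimator = c("histogram", "kernel"), bandwidth = NULL,
                  fit_range = NULL, classify_factor = 3, n_batches = 20L) {
  estimator <- match.arg(estimator)
  if (inherits(series, "km_series")) dt <- series$dt
  moments <- conditional_moments(series, n_max = n_max, lag = lag,
                                 bins = bins, range = range,
                                 min_count = min_count, estimator = estimator,
                                 bandwidth = bandwidth, dt = dt)
  naive <- suppressWarnings(km_coefficients(moments, order_m = 1L))
  corrected <- km_coefficients(moments, order_m = "full")
  if (is.null(fit_range)) fit_range <- .fit_range_default(corrected)
  drift <- fit_linear_drift(corrected, fit_range)
  se <- NULL; classification <- NULL; params <- NULL
  if (n_max >= 6L) {
    se <- km_batch_se(series, corrected, fit_range = fit_range,
                      n_batches = n_batches, dt = dt)
    classification <- classify_process(corrected, se = se,
                                       fit_range = fit_range,
                                       factor = classify_factor)
    params <- if (classification$verdict == "jump_diffusion") {
      recover_jump(corrected, fit_range)
    } else {
      Dbar <- km_average(corrected, fit_range)
      structure(list(a_hat = drift$a_hat, b2_hat = 2 * Dbar[[2]],
                     s_hat = NA_real_, lambda_hat = NA_real_, Dbar = Dbar,
                     fit_range = fit_range,
                     flags = "jump terms absent (classified as diffusion)"),
                class = "km_jump_params")
    }
  }
  structure(list(moments = moments, naive = naive, corrected = corrected,
                 drift = drift, classification = classification,
                 params = params, se = se, dt = dt, lag = lag,
                 fit_range = fit_range, n = length(.series_values(series))),
            class = "kmfit")
}

#' @export
print.kmfit <- function(x, ...) {
  cat("finite-time corrected Kramers-Moyal fit\n")
  cat(sprintf("  %d samples at dt = %g (tau = %g)\n", x$n, x$dt,
              x$moments$tau))
  if (!is.null(x$classification)) {
    cat(sprintf("  dynamics: %s\n", x$classification$verdict))
  }
  cat(sprintf("  drift slope a_hat = %.5g\n", x$drift$a_hat))
  if (!is.null(x$params)) {
    cat(sprintf("  diffusion b2_hat = %.5g\n", x$params$b2_hat))
    if (is.finite(x$params$s_hat)) {
      cat(sprintf("  jumps: lambda_hat = %.5g, s_hat = %.5g\n",
                  x$params$lambda_hat, x$params$s_hat))
    }
  }
  invisible(x)
}

#' @export
summary.kmfit <- function(object, ...) {
  x <- object
  cat("finite-time corrected Kramers-Moyal fit\n")
  cat(sprintf("  samples: %d, dt = %g, lag = %d, tau = %g\n",
              x$n, x$dt, x$lag, x$moments$tau))
  cat(sprintf("  bins: %d (%d excluded), estimator: %s\n",
              length(x$moments$bin_centers), sum(x$moments$excluded),
              x$moments$estimator_kind))
  cat(sprintf("  fit range: [%.4g, %.4g]\n", x$fit_range[1], x$fit_range[2]))
  Dn <- km_average(x$naive, x$fit_range)
  Dc <- km_average(x$corrected, x$fit_range)
  tabl <- cbind(naive = Dn, corrected = Dc,
                se = if (!is.null(x$se)) x$se else rep(NA, length(Dc)))
  cat("\n  occupancy-weighted average coefficients:\n")
  print(signif(tabl, 5))
  if (!is.null(x$classification)) {
    cat(sprintf("\n  classification: %s (Dbar4/se4 = %.3g, threshold %g)\n",
                x$classification$verdict, x$classification$ratio,
                x$classification$factor))
  }
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @export
coef.kmfit <- function(object, ...) {
  p <- object$params
  if (is.null(p)) {
    return(c(a = object$drift$a_hat, b2 = NA, lambda = NA, s = NA))
  }
  c(a = p$a_hat, b2 = p$b2_hat, lambda = p$lambda_hat, s = p$s_hat)
}

#' Plot estimated KM coefficients against state
#'
#' One panel per requested coefficient order, naive (order-1) versus
#' full-order corrected per-bin values over the included bins.
#'
#' @param x a `kmfit`.
#' @param orders coefficient orders to draw (default `c(2, 4, 6)` clipped to
#'   what was estimated).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kmfit <- function(x, orders = c(2L, 4L, 6L), ...) {
  orders <- orders[orders <= ncol(x$corrected$D)]
  old <- graphics::par(mfrow = c(1, length(orders)))
  on.exit(graphics::par(old))
  sel <- !x$corrected$excluded
  xx <- x$corrected$bin_centers[sel]
  for (n in orders) {
    y1 <- x$naive$D[sel, n]
    y2 <- x$corrected$D[sel, n]
    ylim <- range(c(y1, y2), finite = TRUE)
    graphics::plot(xx, y1, type = "b", pch = 1, col = "grey50", ylim = ylim,
                   xlab = "x", ylab = sprintf("D%d(x)", n), ...)
    graphics::lines(xx, y2, type = "b", pch = 16, col = "black")
    graphics::abline(h = 0, lty = 3)
    graphics::legend("topright", bty = "n", pch = c(1, 16),
                     col = c("grey50", "black"),
                     legend = c("order 1", "full order"))
  }
  invisible(x)
}

#' Predict drift and diffusion at new states
#'
#' Evaluates the fitted linear drift `-a_hat * x` and the (state-constant)
#' diffusion `b2_hat / 2`-based `D2` at the requested states.
#'
#' @param object a `kmfit`.
#' @param newdata numeric vector of states; defaults to the bin centers.
#' @param ... unused.
#' @return data frame with columns `x`, `drift`, `D2`.
#' @export
predict.kmfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$corrected$bin_centers
  b2 <- if (!is.null(object$params)) object$params$b2_hat else NA_real_
  sl <- if (is.finite(object$params$lambda_hat %||% NA)) {
    object$params$s_hat * object$params$lambda_hat
  } else 0
  data.frame(x = newdata,
             drift = object$drift$intercept - object$drift$a_hat * newdata,
             D2 = rep((b2 + sl) / 2, length(newdata)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate from a fitted model
#'
#' Draws new trajectories from the recovered parameters (drift slope,
#' diffusion, and jump parameters when detected), using the fitted sampling
#' interval.
#'
#' @param object a `kmfit`.
#' @param nsim number of trajectories.
#' @param seed integer seed for the first trajectory (incremented per
#'   trajectory).
#' @param n_steps steps per trajectory; default matches the fitted series.
#' @param ... unused.
#' @return A `km_series` for `nsim = 1`, else a list of them.
#' @export
simulate.kmfit <- function(object, nsim = 1, seed = 1L, n_steps = NULL, ...) {
  p <- object$params
  if (is.null(p)) stop("fit carries no recovered parameters (n_max < 6)")
  if (is.null(n_steps)) n_steps <- object$n - 1L
  jump <- is.finite(p$s_hat) && is.finite(p$lambda_hat)
  spec <- jd_spec(a = p$a_hat, b = sqrt(max(p$b2_hat, 0)),
                  lambda = if (jump) p$lambda_hat else 0,
                  s = if (jump) p$s_hat else 0,
                  dt = object$dt)
  out <- lapply(seq_len(nsim), function(i) {
    simulate_jd(spec, n_steps = n_steps, seed = as.integer(seed) + i - 1L)
  })
  if (nsim == 1) out[[1]] else out
}
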