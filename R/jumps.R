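# Recovery of jump-diffusion parameters from corrected KM coefficients.
#
# For the mean-reverting process with constant diffusion b and Poissonian
# jumps of rate lambda and Gaussian amplitude variance s:
#   D1(x)    = -a x
#   D2(x)    = (b^2 + s lambda) / 2
#   D_{2n}(x) = s^n lambda / (2^n n!)       (n >= 1)
# so  s = 6 D6 / D4,  lambda = 8 D4 / s^2,  b^2 = 2 D2 - s lambda.

.fit_range_default <- function(estimate) {
  tab <- estimate$table
  # central range: mean +/- 2 sd of the state distribution, reconstructed
  # from the bin occupancy
  w <- tab$counts
  mu <- sum(tab$bin_centers * w) / sum(w)
  sdx <- sqrt(sum((tab$bin_centers - mu)^2 * w) / sum(w))
  c(mu - 2 * sdx, mu + 2 * sdx)
}

.bins_in_range <- function(estimate, fit_range) {
  inr <- estimate$bin_centers >= fit_range[1] &
    estimate$bin_centers <= fit_range[2]
  inr & !estimate$excluded
}

#' Occupancy-weighted average of KM coefficients over a state range
#'
#' Jumps in the supported model are state-independent, so `D2`, `D4`, `D6`
#' are constants; averaging the per-bin estimates (weighted by bin
#' occupancy) over a central range stabilises the ratios used for parameter
#' recovery.
#'
#' @param estimate a `km_estimate`.
#' @param fit_range numeric length-2 state interval; default mean +/- 2 sd
#'   of the state distribution.
#' @return named numeric vector of averaged coefficients `D1...Dn`.
#' @export
km_average <- function(estimate, fit_range = NULL) {
  stopifnot(inherits(estimate, "km_estimate"))
  if (is.null(fit_range)) fit_range <- .fit_range_default(estimate)
  sel <- .bins_in_range(estimate, fit_range)
  if (!any(sel)) stop("no included bins inside fit_range")
  w <- estimate$counts[sel]
  apply(estimate$D[sel, , drop = FALSE], 2,
        function(col) sum(col * w) / sum(w))
}

#' Linear drift fit
#'
#' Least-squares fit of the estimated drift `D1(x)` against `x` over the
#' included bins inside `fit_range`; for a mean-reverting drift `-a x` the
#' recovered strength is minus the slope.
#'
#' @param estimate a `km_estimate`.
#' @param fit_range numeric length-2 state interval; default mean +/- 2 sd.
#' @return list with `a_hat` (minus the slope), `intercept`, `n_bins`, and
#'   `fit_range`.
#' @export
fit_linear_drift <- function(estimate, fit_range = NULL) {
  stopifnot(inherits(estimate, "km_estimate"))
  if (is.null(fit_range)) fit_range <- .fit_range_default(estimate)
  sel <- .bins_in_range(estimate, fit_range)
  if (sum(sel) < 3L) stop("need at least 3 included bins inside fit_range")
  xx <- estimate$bin_centers[sel]
  yy <- estimate$D[sel, 1]
  fit <- stats::lm(yy ~ xx)
  list(a_hat = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_bins = sum(sel), fit_range = fit_range)
}

#' Recover jump-diffusion parameters from corrected coefficients
#'
#' Inverts the constant-jump relations on occupancy-weighted averages of the
#' full-order `D2`, `D4`, `D6`: `s_hat = 6 Dbar6 / Dbar4`,
#' `lambda_hat = 8 Dbar4 / s_hat^2`, `b2_hat = 2 Dbar2 -
#' s_hat * lambda_hat`. If `Dbar4` or `Dbar6` is non-positive (as happens
#' for purely diffusive data through sampling noise), jump inference is
#' suppressed: `s_hat` and `lambda_hat` are reported absent (`NA`) with a
#' flag and `b2_hat = 2 Dbar2`.
#'
#' @param estimate a `km_estimate` containing at least `D2`, `D4`, `D6`.
#' @param fit_range numeric length-2 state interval; default mean +/- 2 sd.
#' @return list of class `km_jump_params`: `a_hat`, `b2_hat`, `s_hat`,
#'   `lambda_hat`, `Dbar` (the averaged coefficients), `fit_range`, `flags`.
#' @examples
#' # exact coefficients of b = 0.5, s = 0.75, lambda = 0.6:
#' # D2 = 0.35, D4 = 0.0421875, D6 = 0.00527344
#' @export
recover_jump <- function(estimate, fit_range = NULL) {
  stopifnot(inherits(estimate, "km_estimate"))
  if (ncol(estimate$D) < 6L) {
    stop("estimate must contain D2, D4 and D6 (n_max >= 6)")
  }
  if (is.null(fit_range)) fit_range <- .fit_range_default(estimate)
  Dbar <- km_average(estimate, fit_range)
  a_hat <- fit_linear_drift(estimate, fit_range)$a_hat
  flags <- character(0)
  if (Dbar[4] <= 0 || Dbar[6] <= 0) {
    flags <- c(flags, "jump terms absent (Dbar4 or Dbar6 <= 0)")
    s_hat <- NA_real_; lambda_hat <- NA_real_
    b2_hat <- 2 * Dbar[[2]]
  } else {
    s_hat <- 6 * Dbar[[6]] / Dbar[[4]]
    lambda_hat <- 8 * Dbar[[4]] / s_hat^2
    b2_hat <- 2 * Dbar[[2]] - s_hat * lambda_hat
    if (b2_hat < 0) flags <- c(flags, "negative b2_hat (jump terms exceed 2*Dbar2)")
  }
  structure(list(a_hat = a_hat, b2_hat = b2_hat, s_hat = s_hat,
                 lambda_hat = lambda_hat, Dbar = Dbar,
                 fit_range = fit_range, flags = flags),
            class = "km_jump_params")
}

#' @export
print.km_jump_params <- function(x, ...) {
  cat("recovered jump-diffusion parameters\n")
  cat(sprintf("  a_hat      = %.6g\n", x$a_hat))
  cat(sprintf("  b2_hat     = %.6g (b_hat = %.6g)\n", x$b2_hat,
              sqrt(max(x$b2_hat, 0))))
  cat(sprintf("  s_hat      = %.6g\n", x$s_hat))
  cat(sprintf("  lambda_hat = %.6g\n", x$lambda_hat))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Batch-means standard errors of the averaged coefficients
#'
#' Splits the series into `n_batches` contiguous blocks, re-estimates the
#' occupancy-weighted averages `Dbar_n` on each block (with the bin edges of
#' the pooled estimate held fixed), and returns the standard error of the
#' pooled average as `sd(batch values)/sqrt(n_batches)`.
#'
#' @param series the `km_series` (or numeric vector with `dt`) the estimate
#'   was computed from.
#' @param estimate the pooled `km_estimate`.
#' @param fit_range state interval for the averages; default mean +/- 2 sd.
#' @param n_batches number of contiguous batches (default 20).
#' @param dt sampling interval when `series` is a bare vector.
#' @return named numeric vector of standard errors for `Dbar_1...Dbar_n`.
#' @export
km_batch_se <- function(series, estimate, fit_range = NULL, n_batches = 20L,
                        dt = NULL) {
  stopifnot(inherits(estimate, "km_estimate"))
  x <- .series_values(series)
  if (inherits(series, "km_series")) dt <- series$dt
  tab <- estimate$table
  if (is.null(fit_range)) fit_range <- .fit_range_default(estimate)
  nb <- length(tab$bin_centers)
  rng <- c(tab$bin_edges[1], tab$bin_edges[nb + 1])
  cuts <- floor(seq(1, length(x) + 1, length.out = n_batches + 1))
  vals <- matrix(NA_real_, n_batches, ncol(estimate$D))
  for (i in seq_len(n_batches)) {
    seg <- x[cuts[i]:(cuts[i + 1] - 1)]
    if (length(seg) <= tab$lag + 1) next
    cm <- conditional_moments(seg, n_max = tab$n_max, lag = tab$lag,
                              bins = nb, range = rng,
                              min_count = 1L, dt = dt)
    est <- suppressWarnings(km_coefficients(cm, order_m = estimate$order_m))
    sel <- est$bin_centers >= fit_range[1] & est$bin_centers <= fit_range[2] &
      est$counts > 0
    if (!any(sel)) next
    w <- est$counts[sel]
    vals[i, ] <- apply(est$D[sel, , drop = FALSE], 2,
                       function(col) sum(col * w, na.rm = TRUE) / sum(w))
  }
  ok <- stats::complete.cases(vals)
  se <- apply(vals[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
  stats::setNames(se, colnames(estimate$D))
}

#' Classify a series as diffusion or jump-diffusion
#'
#' Higher even KM coefficients vanish for purely diffusive processes once
#' finite-time corrected, while jumps make them strictly positive
#' (`D4 = s^2 lambda / 8`). The rule: report `"jump_diffusion"` when the
#' averaged full-order `Dbar4` exceeds `factor` times its standard error,
#' else `"diffusion"`. Standard errors may be supplied directly or computed
#' by batch means from the series.
#'
#' @param estimate a full-order `km_estimate` with `n_max >= 6`.
#' @param se named numeric vector of standard errors of the averaged
#'   coefficients (as from [km_batch_se()]); computed from `series` when
#'   omitted.
#' @param series the source series, needed if `se` is missing.
#' @param fit_range state interval; default mean +/- 2 sd.
#' @param factor detection threshold in standard errors (default 3).
#' @param n_batches batches for [km_batch_se()] when `se` is computed here.
#' @return list of class `km_classification`: `verdict`
#'   (`"diffusion"` or `"jump_diffusion"`), `Dbar4`, `se4`, `Dbar6`, `se6`,
#'   `ratio`, `factor`, `fit_range`.
#' @export
classify_process <- function(estimate, se = NULL, series = NULL,
                             fit_range = NULL, factor = 3, n_batches = 20L) {
  stopifnot(inherits(estimate, "km_estimate"))
  if (is.null(fit_range)) fit_range <- .fit_range_default(estimate)
  Dbar <- km_average(estimate, fit_range)
  if (is.null(se)) {
    if (is.null(series)) stop("supply either se or the source series")
    se <- km_batch_se(series, estimate, fit_range = fit_range,
                      n_batches = n_batches)
  }
  se4 <- se[["D4"]]; se6 <- if ("D6" %in% names(se)) se[["D6"]] else NA_real_
  ratio <- if (se4 > 0) Dbar[[4]] / se4 else if (Dbar[[4]] > 0) Inf else 0
  verdict <- if (is.finite(ratio) && ratio > factor || identical(ratio, Inf))
    "jump_diffusion" else "diffusion"
  if (Dbar[[4]] <= 0) verdict <- "diffusion"
  structure(list(verdict = verdict, Dbar4 = Dbar[[4]], se4 = se4,
                 Dbar6 = Dbar[[6]], se6 = se6, ratio = ratio,
                 factor = factor, fit_range = fit_range),
            class = "km_classification")
}

#' @export
print.km_classification <- function(x, ...) {
  cat(sprintf("classification: %s\n", x$verdict))
  cat(sprintf("  Dbar4 = %.4g (se %.4g, ratio %.3g, threshold %g)\n",
              x$Dbar4, x$se4, x$ratio, x$factor))
  cat(sprintf("  Dbar6 = %.4g (se %.4g)\n", x$Dbar6, x$se6))
  invisible(x)
}

#' Flat key=value text report of recovered parameters
#'
#' @param params a `km_jump_params`.
#' @param classification optional `km_classification` to include.
#' @param path optional output file; when omitted the lines are returned.
#' @return character vector of report lines, invisibly when written.
#' @export
write_jump_report <- function(params, classification = NULL, path = NULL) {
  stopifnot(inherits(params, "km_jump_params"))
  lines <- c(
    sprintf("a_hat=%.17g", params$a_hat),
    sprintf("b2_hat=%.17g", params$b2_hat),
    sprintf("s_hat=%.17g", params$s_hat),
    sprintf("lambda_hat=%.17g", params$lambda_hat),
    sprintf("fit_range=%.17g,%.17g", params$fit_range[1], params$fit_range[2]),
    sprintf("flags=%s", paste(params$flags, collapse = ";"))
  )
  if (!is.null(classification)) {
    lines <- c(lines,
               sprintf("verdict=%s", classification$verdict),
               sprintf("Dbar4=%.17g", classification$Dbar4),
               sprintf("se4=%.17g", classification$se4))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
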