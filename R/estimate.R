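# Non-parametric estimation of conditional moments and finite-time corrected
# KM coefficients from a uniformly sampled time series.

.series_values <- function(series) {
  if (inherits(series, "km_series")) return(series$values)
  if (is.numeric(series)) return(as.numeric(series))
  stop("series must be a km_series or numeric vector")
}

#' Empirical conditional moments on a state partition
#'
#' For each state bin `B` (half-open intervals `[lo, hi)`) the n-th
#' conditional moment at lag `tau = lag * dt` is the sample average of
#' `(X_{t+lag} - X_t)^n` over all `t` with `X_t` in `B` -- the finite-lag
#' estimator of `E[(X(t+tau) - x')^n | X(t) = x']`. Bins holding fewer than
#' `min_count` transitions are flagged excluded (their moments are still
#' reported). A Nadaraya-Watson alternative with an Epanechnikov kernel
#' evaluates the same moments at the bin centers with kernel weights.
#'
#' @param series a `km_series` from [simulate_jd()]/[read_series()], or a
#'   numeric vector (then `dt` must be given).
#' @param n_max highest moment order, `>= 1` (default 6).
#' @param lag integer lag in samples, `>= 1`; `tau = lag * dt`.
#' @param bins number of equal-width bins (default 30).
#' @param range numeric length-2 state range; default `mean(x) +/- 4 sd(x)`.
#' @param min_count occupancy threshold below which a bin is flagged
#'   excluded (default 100).
#' @param estimator `"histogram"` (default) or `"kernel"`
#'   (Nadaraya-Watson, Epanechnikov kernel).
#' @param bandwidth kernel bandwidth; default Silverman's rule on the state
#'   distribution. Ignored for the histogram estimator.
#' @param dt sampling interval, required when `series` is a bare vector.
#' @return An object of class `km_moments`: list with `bin_edges`,
#'   `bin_centers`, `state_mean` (occupancy-weighted mean state per bin),
#'   `counts`, `excluded`, `tau`, `dt`, `lag`, `n_max`, `estimator_kind`,
#'   `min_count`, `bandwidth` and `moments` (a `bins x n_max` matrix,
#'   columns `M1...Mn`).
#' @examples
#' ts <- simulate_jd(jd_spec(a = 1, b = 0.5, dt = 0.1), 5e4, seed = 1)
#' cm <- conditional_moments(ts, n_max = 4)
#' @export
conditional_moments <- function(series, n_max = 6L, lag = 1L, bins = 30L,
                                range = NULL, min_count = 100L,
                                estimator = c("histogram", "kernel"),
                                bandwidth = NULL, dt = NULL) {
  estimator <- match.arg(estimator)
  x <- .series_values(series)
  if (inherits(series, "km_series")) dt <- series$dt
  if (is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("a positive sampling interval dt is required")
  }
  if (n_max < 1 || n_max != round(n_max)) stop("n_max must be a positive integer")
  if (lag < 1 || lag != round(lag)) stop("lag must be a positive integer")
  if (length(x) < 2L) stop("series must contain at least 2 values")
  if (lag >= length(x)) stop("lag must be smaller than the series length")
  n <- length(x) - lag
  state <- x[seq_len(n)]
  incr <- x[seq_len(n) + lag] - state
  if (is.null(range)) {
    mu <- mean(x); sdx <- stats::sd(x)
    if (sdx == 0) sdx <- max(abs(mu), 1) * 1e-8 # degenerate constant series
    range <- c(mu - 4 * sdx, mu + 4 * sdx)
  }
  stopifnot(length(range) == 2L, range[1] < range[2])
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  moments <- matrix(NA_real_, bins, n_max,
                    dimnames = list(NULL, paste0("M", seq_len(n_max))))
  if (estimator == "histogram") {
    idx <- findInterval(state, edges, rightmost.closed = FALSE, left.open = FALSE)
    inb <- idx >= 1L & idx <= bins & state < edges[length(edges)]
    idx <- idx[inb]
    counts <- tabulate(idx, nbins = bins)
    d <- incr[inb]
    dn <- rep(1, length(d))
    occupied <- counts > 0L
    for (m in seq_len(n_max)) {
      dn <- dn * d
      sums <- rowsum(dn, idx, reorder = TRUE)
      moments[sort(unique(idx)), m] <- sums[, 1]
    }
    moments[occupied, ] <- moments[occupied, , drop = FALSE] / counts[occupied]
    state_mean <- rep(NA_real_, bins)
    state_mean[sort(unique(idx))] <- rowsum(state[inb], idx, reorder = TRUE)[, 1]
    state_mean[occupied] <- state_mean[occupied] / counts[occupied]
  } else {
    if (is.null(bandwidth)) {
      bandwidth <- 0.9 * min(stats::sd(state),
                             stats::IQR(state) / 1.34) * length(state)^(-1 / 5)
      if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- diff(range) / bins
    }
    counts <- integer(bins)
    state_mean <- rep(NA_real_, bins)
    for (bnum in seq_len(bins)) {
      u <- (state - centers[bnum]) / bandwidth
      sel <- abs(u) < 1
      counts[bnum] <- sum(sel)
      if (counts[bnum] > 0L) {
        w <- 0.75 * (1 - u[sel]^2)
        d <- incr[sel]
        dn <- rep(1, length(d))
        sw <- sum(w)
        state_mean[bnum] <- sum(w * state[sel]) / sw
        for (m in seq_len(n_max)) {
          dn <- dn * d
          moments[bnum, m] <- sum(w * dn) / sw
        }
      }
    }
  }
  structure(list(bin_edges = edges, bin_centers = centers,
                 state_mean = state_mean,
                 counts = as.integer(counts),
                 excluded = counts < min_count,
                 tau = lag * dt, dt = dt, lag = as.integer(lag),
                 n_max = as.integer(n_max), estimator_kind = estimator,
                 min_count = as.integer(min_count),
                 bandwidth = if (estimator == "kernel") bandwidth else NA_real_,
                 moments = moments),
            class = "km_moments")
}

#' @export
print.km_moments <- function(x, ...) {
  cat(sprintf("conditional moments: %d bins, tau = %g (lag %d), M1..M%d, %s estimator\n",
              length(x$bin_centers), x$tau, x$lag, x$n_max, x$estimator_kind))
  cat(sprintf("  %d bins excluded (count < %d)\n", sum(x$excluded), x$min_count))
  invisible(x)
}

#' Finite-time corrected KM coefficients from conditional moments
#'
#' Applies the numeric Bell inversion ([invert_numeric()]) bin-wise.
#' `order_m = 1` is the uncorrected estimator `M_n/(n! tau)`; `order_m = n`
#' (or `"full"`) the complete correction. The drift `D1` is identical at
#' every order. Negative higher even coefficients can occur through sampling
#' noise; they are reported as-is and flagged, never clipped.
#'
#' @param table a `km_moments` object.
#' @param order_m correction order: positive integer or `"full"` (default).
#' @return An object of class `km_estimate`: list with `bin_centers`,
#'   `counts`, `excluded`, `tau`, `order_m`, `D` (matrix, columns
#'   `D1...Dn`), `negative_flag` (bins where `D2` or `D4` came out
#'   negative) and `table` (the source moments, for provenance).
#' @export
km_coefficients <- function(table, order_m = "full") {
  stopifnot(inherits(table, "km_moments"))
  full <- identical(order_m, "full") || is.infinite(order_m)
  ord <- if (full) Inf else {
    if (!is.numeric(order_m) || order_m < 1 || order_m != round(order_m)) {
      stop("order_m must be a positive integer or \"full\"")
    }
    if (order_m > table$n_max) {
      stop("order_m exceeds the available moment order n_max = ", table$n_max)
    }
    order_m
  }
  D <- invert_numeric(table$moments, tau = table$tau, order_m = ord)
  colnames(D) <- paste0("D", seq_len(ncol(D)))
  neg <- rep(FALSE, nrow(D))
  for (j in intersect(c(2L, 4L), seq_len(ncol(D)))) {
    # ignore cancellation residue at the scale of the uncorrected estimate
    tol <- 1e-10 * (abs(table$moments[, j]) / (factorial(j) * table$tau) +
                      .Machine$double.xmin)
    neg <- neg | (!is.na(D[, j]) & D[, j] < -tol)
  }
  if (any(neg & !table$excluded)) {
    warning(sum(neg & !table$excluded),
            " included bin(s) have negative D2 or D4 (sampling noise); ",
            "values reported unclipped")
  }
  structure(list(bin_centers = table$bin_centers, counts = table$counts,
                 excluded = table$excluded, tau = table$tau,
                 order_m = if (full) "full" else as.integer(ord),
                 D = D, negative_flag = neg, table = table),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("KM coefficient estimate: %d bins, tau = %g, order = %s, D1..D%d\n",
              length(x$bin_centers), x$tau, as.character(x$order_m), ncol(x$D)))
  invisible(x)
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a moments table or coefficient estimate to delimited text
#'
#' Tab-separated with `#`-prefixed header recording `dt`, `tau`, `lag`,
#' `estimator_kind`, binning and (for estimates) `order_m`; columns
#' `bin_lo`, `bin_hi`, `center`, `state_mean`, `count`, `excluded`, then
#' `M1...Mn` or `D1...Dn`. Excluded bins are serialized with their flag, not dropped,
#' and a write -> read -> write cycle is byte-identical.
#'
#' @param x a `km_moments` or `km_estimate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_km_table <- function(x, path) {
  if (inherits(x, "km_moments")) {
    tab <- x; vals <- x$moments; kind <- "moments"; order_m <- NA
  } else if (inherits(x, "km_estimate")) {
    tab <- x$table; vals <- x$D; kind <- "coefficients"; order_m <- x$order_m
  } else stop("x must be a km_moments or km_estimate")
  header <- c(
    sprintf("# kind=%s", kind),
    sprintf("# dt=%.17g", tab$dt),
    sprintf("# tau=%.17g", tab$tau),
    sprintf("# lag=%d", tab$lag),
    sprintf("# n_max=%d", tab$n_max),
    sprintf("# estimator_kind=%s", tab$estimator_kind),
    sprintf("# bins=%d", length(tab$bin_centers)),
    sprintf("# range=%.17g,%.17g", tab$bin_edges[1],
            tab$bin_edges[length(tab$bin_edges)]),
    sprintf("# min_count=%d", tab$min_count),
    if (!is.na(tab$bandwidth)) sprintf("# bandwidth=%.17g", tab$bandwidth),
    if (kind == "coefficients") sprintf("# order_m=%s", as.character(order_m))
  )
  excl <- if (kind == "coefficients") x$excluded else tab$excluded
  cols <- colnames(vals)
  lines <- c(header,
             paste(c("bin_lo", "bin_hi", "center", "state_mean", "count",
                     "excluded", cols), collapse = "\t"))
  nb <- length(tab$bin_centers)
  for (i in seq_len(nb)) {
    lines <- c(lines, paste(c(
      .fmt_num(tab$bin_edges[i]), .fmt_num(tab$bin_edges[i + 1]),
      .fmt_num(tab$bin_centers[i]), .fmt_num(tab$state_mean[i]),
      tab$counts[i], as.integer(excl[i]),
      vapply(vals[i, ], .fmt_num, character(1))), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a table written by [write_km_table()]
#'
#' @param path input file path.
#' @return A `km_moments` or `km_estimate`, matching what was written.
#' @export
read_km_table <- function(path) {
  lines <- readLines(path)
  is_h <- startsWith(lines, "#")
  kv <- list()
  for (h in lines[is_h]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  body <- lines[!is_h]
  colnames_ <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  mat <- do.call(rbind, lapply(rows, function(r) {
    r[r == "NA"] <- NA_character_ # empty bins carry no moment values
    as.numeric(r)
  }))
  colnames(mat) <- colnames_
  vcols <- setdiff(colnames_, c("bin_lo", "bin_hi", "center", "state_mean",
                                "count", "excluded"))
  edges <- c(mat[, "bin_lo"], mat[nrow(mat), "bin_hi"])
  vals <- mat[, vcols, drop = FALSE]
  tab <- structure(list(
    bin_edges = edges, bin_centers = mat[, "center"],
    state_mean = mat[, "state_mean"],
    counts = as.integer(mat[, "count"]),
    excluded = mat[, "excluded"] > 0,
    tau = as.numeric(kv$tau), dt = as.numeric(kv$dt),
    lag = as.integer(kv$lag), n_max = as.integer(kv$n_max),
    estimator_kind = kv$estimator_kind,
    min_count = as.integer(kv$min_count),
    bandwidth = if (!is.null(kv$bandwidth)) as.numeric(kv$bandwidth) else NA_real_,
    moments = vals), class = "km_moments")
  if (identical(kv$kind, "coefficients")) {
    ord <- if (identical(kv$order_m, "full")) "full" else as.integer(kv$order_m)
    tab$moments <- NULL
    return(structure(list(bin_centers = mat[, "center"],
                          counts = as.integer(mat[, "count"]),
                          excluded = mat[, "excluded"] > 0,
                          tau = as.numeric(kv$tau), order_m = ord,
                          D = vals,
                          negative_flag = rep(NA, nrow(mat)),
                          table = tab),
                     class = "km_estimate"))
  }
  tab
}
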