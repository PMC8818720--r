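#' Time series of WSS flatmaps over one cardiac cycle
#'
#' @param frames list of 3-channel WSS [flatmap()]s, time-ordered.
#' @param times frame times in ms, strictly increasing, spanning one cycle.
#' @return object of class `wss_series`; its `mask` is the conjunction of
#'   the frame masks.
#' @export
wss_series <- function(frames, times) {
  if (length(frames) < 2L) stop("a WSS series needs at least 2 frames")
  if (length(times) != length(frames)) stop("times must match frames")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  d <- dim(frames[[1]]$values)
  mask <- frames[[1]]$mask
  for (f in frames) {
    if (!all(dim(f$values) == d)) stop("frames must share dimensions")
    mask <- mask & f$mask
  }
  structure(list(frames = frames, times = times, mask = mask),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series: %d frames over %.0f ms, %d x %d>\n",
              length(x$frames), diff(range(x$times)),
              dim(x$frames[[1]]$values)[1], dim(x$frames[[1]]$values)[2]))
  invisible(x)
}

# trapezoidal quadrature weights over the frame times
trapz_weights <- function(times) {
  dt <- diff(times)
  n <- length(times)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

# stack per-frame magnitudes / components into arrays
series_mags <- function(series) {
  vapply(series$frames, flatmap_magnitude,
         matrix(0, dim(series$frames[[1]]$values)[1],
                dim(series$frames[[1]]$values)[2]))
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-node time average of the WSS magnitude over the cardiac cycle,
#' `TAWSS = (1/T) \int_0^T |wss| dt`, computed with the trapezoidal rule
#' over the series' frame times.
#'
#' @param series a [wss_series()].
#' @return 1-channel [flatmap()] in Pa.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  w <- trapz_weights(series$times)
  T <- diff(range(series$times))
  mags <- series_mags(series)
  out <- matrix(0, dim(mags)[1], dim(mags)[2])
  for (i in seq_along(w)) out <- out + w[i] * mags[, , i]
  flatmap(out / T, mask = series$mask, channel_names = "tawss")
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 (1 - |\int wss dt| / \int |wss| dt)` per node, with both
#' integrals over one cardiac cycle by the trapezoidal rule. 0 means the WSS
#' direction never changes; 0.5 means a full 180-degree reversal of equal
#' magnitude. Nodes whose magnitude integral vanishes are masked.
#'
#' @param series a [wss_series()].
#' @return 1-channel [flatmap()] with values in `[0, 0.5]`.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  w <- trapz_weights(series$times)
  d <- dim(series$frames[[1]]$values)
  vec <- array(0, d)
  magint <- matrix(0, d[1], d[2])
  for (i in seq_along(w)) {
    vec <- vec + w[i] * series$frames[[i]]$values
    magint <- magint + w[i] * flatmap_magnitude(series$frames[[i]])
  }
  vecmag <- sqrt(apply(vec^2, c(1, 2), sum))
  ok <- magint > 0
  val <- matrix(0, d[1], d[2])
  val[ok] <- 0.5 * (1 - vecmag[ok] / magint[ok])
  flatmap(val, mask = series$mask & ok, channel_names = "osi")
}

#' Per-frame WSS error metrics
#'
#' Point-to-point comparison of predicted and reference WSS magnitude over
#' the shared valid nodes: mean absolute error (Pa), relative error (mean
#' absolute difference as a percentage of the peak reference magnitude in
#' the frame), and Pearson correlation of the magnitude images (pattern
#' similarity).
#'
#' @param pred,ref 3-channel WSS [flatmap()]s.
#' @return list with `mae` (Pa), `rel_error` (percent), `pearson`, and
#'   `n` (valid nodes). `pearson` is `NA` (with a warning) for a constant
#'   reference.
#' @export
frame_errors <- function(pred, ref) {
  mask <- pred$mask & ref$mask
  if (sum(mask) < 2L) stop("need at least 2 shared valid nodes")
  pm <- flatmap_magnitude(pred)[mask]
  rm_ <- flatmap_magnitude(ref)[mask]
  mae <- mean(abs(pm - rm_))
  peak <- max(rm_)
  rel <- if (peak > 0) mae / peak * 100 else NA_real_
  pearson <- if (stats::sd(rm_) == 0 || stats::sd(pm) == 0) {
    warning("constant magnitude image: Pearson correlation undefined")
    NA_real_
  } else stats::cor(pm, rm_)
  list(mae = mae, rel_error = rel, pearson = pearson, n = sum(mask))
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-measure, absolute-agreement intraclass correlation from the
#' two-way (subjects x raters) ANOVA decomposition: with mean squares for
#' rows (subjects) MSR, columns (raters) MSC and error MSE and k = 2 raters,
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`. Unlike
#' Pearson correlation, a constant offset between the two measurements
#' lowers the coefficient.
#'
#' @param x,y paired measurements (two raters), length n >= 3.
#' @return scalar ICC(A,1); `NA` with a warning if both raters are constant.
#' @export
icc_a1 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("ICC needs at least 3 paired values")
  k <- 2
  M <- cbind(x, y)
  grand <- mean(M)
  rowm <- rowMeans(M)
  colm <- colMeans(M)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- sum((M - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  if (den == 0) {
    warning("zero variance in both measurements: ICC undefined")
    return(NA_real_)
  }
  (MSR - MSE) / den
}

#' Bland-Altman agreement statistics
#'
#' @param x,y paired measurements; differences are `y - x`.
#' @return list with `bias` (mean difference), `sd`, and the 95% limits of
#'   agreement `loa_low`/`loa_high` (`bias -/+ 1.96 sd`).
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- y[ok] - x[ok]
  if (length(d) < 2L) stop("need at least 2 paired values")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Ordinary least-squares regression summary
#'
#' Slope, intercept and coefficient of determination of `y ~ x`, as used to
#' compare estimated against reference TAWSS/OSI.
#'
#' @param x,y numeric vectors, n >= 3, `var(x) > 0`.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linreg_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
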