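#' Penalized smoothing spline with a 50% frequency cutoff
#'
#' Smooths an equally spaced series with the discrete analogue of a cubic
#' smoothing spline: the minimizer of
#' \deqn{\sum_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,}
#' a second-difference (Whittaker) penalty. On a unit grid this filter has
#' the analytic amplitude response
#' \deqn{H(f) = 1 / (1 + \lambda\,(2 - 2\cos 2\pi f)^2),}
#' so \code{lambda} is set from the requested wavelength \code{cutoff} at
#' which the response is exactly 0.5 — the standard way dendrochronological
#' smoothing splines are parameterized.
#'
#' @param y Numeric series on an equally spaced grid; interior \code{NA}s are
#'   linearly interpolated before smoothing (leading/trailing \code{NA}s are
#'   preserved).
#' @param cutoff Wavelength (in steps, i.e. years) of 50% frequency response.
#' @return Smoothed series, same length as \code{y}.
#' @export
spline_smooth <- function(y, cutoff) {
  n <- length(y)
  if (n == 0L) return(y)
  if (!is.finite(cutoff) || cutoff <= 2) stop_br("spline_smooth: cutoff must exceed 2 steps")
  idx <- which(!is.na(y))
  if (length(idx) == 0L) return(y)
  lo <- min(idx); hi <- max(idx)
  yy <- y[lo:hi]
  if (anyNA(yy)) {
    ok <- !is.na(yy)
    yy[!ok] <- approx(which(ok), yy[ok], xout = which(!ok))$y
  }
  m <- length(yy)
  out <- y
  if (m < 4L) {
    out[lo:hi] <- mean(yy)
    return(out)
  }
  lambda <- 1 / (2 - 2 * cos(2 * pi / cutoff))^2
  D <- diff(diag(m), differences = 2L)
  A <- diag(m) + lambda * crossprod(D)
  out[lo:hi] <- as.numeric(solve(A, yy))
  out
}

## High-pass a series as the ratio to its smooth (dendro convention for
## removing growth trend before correlation-based quality control).
highpass_ratio <- function(y, cutoff) {
  sm <- spline_smooth(y, cutoff)
  sm[!is.na(sm) & sm <= 0] <- NA_real_
  y / sm
}
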