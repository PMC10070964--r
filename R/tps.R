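# Regularized thin-plate spline interpolation on scattered points.
#
# Classic 2-D TPS: f(p) = a0 + a1 x + a2 y + sum_i w_i phi(|p - p_i|) with
# phi(r) = r^2 log r, solved from the standard augmented linear system. Two
# knobs: `smoothing` (>= 0) is added to the kernel diagonal and trades
# fidelity at the data points for surface stiffness (0 = exact
# interpolation); `tension` rescales distances before the kernel is applied,
# so larger tension makes the surface more local/membrane-like. Both mirror
# the parameter pair of the regularized-spline-with-tension family of
# interpolators. The affine part reproduces constant and planar fields
# exactly at any smoothing.

tps_kernel <- function(r) {
  k <- r
  k[] <- 0
  pos <- r > 0
  k[pos] <- r[pos]^2 * log(r[pos])
  k
}

#' Fit a thin-plate spline to scattered points
#'
#' @param x,y Point coordinates (same CRS units); duplicated locations are
#'   collapsed to their mean value.
#' @param z Observed values.
#' @param tension Distance-scaling tension (> 0); default 40.
#' @param smoothing Non-negative ridge added to the kernel diagonal;
#'   0 gives exact interpolation at the points.
#' @return An object of class `tps_fit`.
#' @export
tps_fit <- function(x, y, z, tension = 40, smoothing = 0) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(list(z = z), by = list(key = key), FUN = mean)
    first <- !duplicated(key)
    x <- x[first]; y <- y[first]
    z <- agg$z[match(key[first], agg$key)]
  }
  n <- length(x)
  if (n < 3L)
    stop("thin-plate spline needs at least 3 distinct points", call. = FALSE)
  if (tension <= 0) stop("`tension` must be positive", call. = FALSE)
  if (smoothing < 0) stop("`smoothing` must be non-negative", call. = FALSE)
  diag_len <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  if (diag_len == 0) stop("all points coincide", call. = FALSE)
  scale <- diag_len / tension
  xs <- x / scale; ys <- y / scale
  d <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
  K <- tps_kernel(d) + diag(smoothing, n)
  P <- cbind(1, xs, ys)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    qr.solve(A, rhs, tol = 1e-12))
  structure(list(x = xs, y = ys, w = sol[seq_len(n)],
                 a = sol[n + 1:3], scale = scale),
            class = "tps_fit")
}

#' Evaluate a fitted thin-plate spline
#'
#' @param fit A [tps_fit()] object.
#' @param x,y Coordinates at which to evaluate (original CRS units).
#' @return Numeric vector of surface values.
#' @export
tps_predict <- function(fit, x, y) {
  xs <- x / fit$scale; ys <- y / fit$scale
  d <- sqrt(outer(xs, fit$x, "-")^2 + outer(ys, fit$y, "-")^2)
  drop(tps_kernel(d) %*% fit$w) + fit$a[1] + fit$a[2] * xs + fit$a[3] * ys
}
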