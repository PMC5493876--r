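#' Equidistant B-spline basis
#'
#' Evaluates a B-spline basis on `n_knots` equidistant knots spanning the
#' range of the training values, extended by `degree` extra knots on each
#' side with the same spacing, giving `n_knots + degree - 1` basis
#' functions. Rows sum to one (partition of unity) inside the knot range;
#' outside it the basis is continued by linear extrapolation from the
#' nearest boundary, so fitted smooths extrapolate linearly.
#'
#' The knot range defaults to `range(x)`; pass `xr` to evaluate a basis
#' anchored on a training range at new values.
#'
#' @param x numeric vector of evaluation points (finite).
#' @param n_knots number of knots spanning the range (>= 2).
#' @param degree polynomial degree (default 3, cubic).
#' @param xr optional length-2 training range defining the knots.
#' @return matrix `length(x)` x `(n_knots + degree - 1)`, with attributes
#'   `knots` (the extended knot sequence), `degree` and `xr`.
#' @export
bspline_basis <- function(x, n_knots = 10L, degree = 3L, xr = range(x)) {
  if (!all(is.finite(x))) stop("x must be finite")
  if (n_knots < 2L) stop("n_knots must be >= 2")
  if (diff(xr) <= 0) stop("x has zero range; cannot place equidistant knots")
  h <- diff(xr) / (n_knots - 1L)
  knots <- seq(xr[1L] - degree * h, xr[2L] + degree * h,
               length.out = n_knots + 2L * degree)
  ord <- degree + 1L
  inside <- x >= xr[1L] & x <= xr[2L]
  B <- matrix(0, length(x), n_knots + degree - 1L)
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(knots, x[inside], ord = ord, outer.ok = TRUE)
  }
  for (side in c(1L, 2L)) {
    out <- if (side == 1L) x < xr[1L] else x > xr[2L]
    if (!any(out)) next
    x0 <- xr[side]
    b0 <- splines::splineDesign(knots, x0, ord = ord, outer.ok = TRUE)
    b1 <- splines::splineDesign(knots, x0, ord = ord, derivs = 1L, outer.ok = TRUE)
    B[out, ] <- rep(1, sum(out)) %o% drop(b0) + (x[out] - x0) %o% drop(b1)
  }
  structure(B, knots = knots, degree = degree, xr = xr)
}

#' Difference penalty matrix for P-splines
#'
#' Builds `K = D'D` where `D` is the `(d - r) x d` matrix of `r`-th order
#' differences of adjacent coefficients, so the quadratic form penalises
#' the summed squared `r`-th differences. For `r = 2` (the default used
#' throughout) the null space is spanned by constant and linear coefficient
#' sequences: as the smoothing parameter grows the fit approaches a
#' straight line.
#'
#' @param d coefficient block size.
#' @param r difference order (default 2), with `d > r >= 1`.
#' @return dense symmetric `penalty_matrix` of kind `"difference2"` (or
#'   `"difference<r>"`), rank deficiency `r`.
#' @export
difference_penalty <- function(d, r = 2L) {
  if (r < 1L) stop("difference order r must be >= 1")
  if (d <= r) stop("block size d must exceed the difference order r")
  D <- diff(diag(d), differences = r)
  penalty_matrix(crossprod(D), kind = paste0("difference", r),
                 rank_deficiency = as.integer(r))
}
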