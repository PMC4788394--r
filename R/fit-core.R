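#' Chord-length parametrization of a data polyline
#'
#' Assigns each data point a parameter proportional to the cumulative
#' Euclidean distance along the polyline, scaled to \eqn{[0, 1]}:
#' \eqn{\theta_0 = 0}, \eqn{\theta_k = \sum_{i \le k} |D_i - D_{i+1}| /
#' \sum_i |D_i - D_{i+1}|}, \eqn{\theta_{m-1} = 1}.
#'
#' @param points m x 2 matrix of ordered data points (m >= 2), consecutive
#'   points distinct.
#' @return numeric vector of m strictly increasing parameters from 0 to 1.
#' @examples
#' chord_length_params(rbind(c(0, 0), c(3, 0), c(3, 4)))  # 0, 3/8, 1
#' @export
chord_length_params <- function(points) {
  pts <- as_points(points)
  m <- nrow(pts)
  if (m < 2L) stop("need at least 2 data points", call. = FALSE)
  d <- row_norms(diff(pts))
  if (any(d == 0)) {
    stop("degenerate data: coincident consecutive points", call. = FALSE)
  }
  th <- c(0, cumsum(d)) / sum(d)
  th[m] <- 1
  th
}

#' Normalized mean squares error of a fitted curve
#'
#' The cost driving the genetic optimization:
#' \deqn{E^2 = \sum_k |s(\theta_k) - D_k|^2 \; / \; \sum_k |D_k|^2.}
#' Note the denominator is the raw (uncentred) sum of squared data norms, so
#' the value depends on the coordinate origin; data in pixel coordinates are
#' compared against the image origin.  The error is 0 exactly when the curve
#' interpolates every data point at its parameter.
#'
#' @param curve either a [rational_segment()] (evaluated at `params`), a
#'   function `f(theta)` returning an n x 2 matrix, or a pre-evaluated
#'   n x 2 matrix of curve points aligned with `points`.
#' @param points m x 2 matrix of data points \eqn{D_k}.
#' @param params parameters \eqn{\theta_k}; defaults to
#'   [chord_length_params()] of `points`.  Ignored when `curve` is a matrix.
#' @return a non-negative scalar.
#' @export
nmse <- function(curve, points, params = NULL) {
  pts <- as_points(points)
  denom <- sum(pts * pts)
  if (denom == 0) {
    stop("NMSE undefined: all data points at the origin", call. = FALSE)
  }
  if (is.null(params)) params <- chord_length_params(pts)
  s <- if (is.matrix(curve)) {
    curve
  } else if (inherits(curve, "rational_segment")) {
    eval_rational(curve, params)
  } else if (is.function(curve)) {
    curve(params)
  } else {
    stop("`curve` must be a rational_segment, a function, or a matrix",
         call. = FALSE)
  }
  if (nrow(s) != nrow(pts)) {
    stop("curve evaluation and data are not aligned", call. = FALSE)
  }
  sum((s - pts)^2) / denom
}

#' Least-squares estimate of the inner numerator coefficients
#'
#' With the segment endpoints pinned (\eqn{A = D_1}, \eqn{D = D_m}) and the
#' weights \eqn{a, b} given, the inner coefficients are estimated by the
#' Q-weighted linearization of the rational residual: minimize
#' \deqn{\sum_k |P(\theta_k) - D_k\,Q(\theta_k)|^2}
#' which is linear in \eqn{B} and \eqn{C} and solves by normal equations
#' (QR).  The solution is exact whenever the data lie on a representable
#' curve at the given parameters.  When `b_fixed` is supplied (a segment
#' whose `B` is dictated by the GC1 link), only `C` is estimated.
#'
#' @param points m x 2 matrix of segment data; first and last rows are the
#'   fixed endpoints.
#' @param params chord-length parameters aligned with `points`.
#' @param a_w,b_w positive denominator weights.
#' @param b_fixed optional planar point: a predetermined `B` coefficient.
#' @return list with components `b_pt` and `c_pt`.
#' @export
least_squares_controls <- function(points, params, a_w, b_w, b_fixed = NULL) {
  pts <- as_points(points)
  m <- nrow(pts)
  th <- as.numeric(params)
  if (length(th) != m) stop("`params` not aligned with `points`", call. = FALSE)
  a_w <- check_positive(a_w, "a_w")
  b_w <- check_positive(b_w, "b_w")
  a_pt <- pts[1L, ]
  d_pt <- pts[m, ]
  om <- 1 - th
  n0 <- om^2; n1 <- om^2 * th; n2 <- om * th^2; n3 <- th^2
  q <- n0 + a_w * n1 + b_w * n2 + n3

  free_b <- is.null(b_fixed)
  x <- if (free_b) cbind(n1, n2) else cbind(n2)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("under-determined least-squares system: too few distinct ",
         "interior data points for the free coefficients", call. = FALSE)
  }
  rhs <- pts * q - outer(n0, a_pt) - outer(n3, d_pt)
  if (!free_b) rhs <- rhs - outer(n1, as_point(b_fixed))
  beta <- qr.coef(qrx, rhs)
  if (free_b) {
    list(b_pt = as.numeric(beta[1L, ]), c_pt = as.numeric(beta[2L, ]))
  } else {
    list(b_pt = as_point(b_fixed), c_pt = as.numeric(beta[1L, ]))
  }
}
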