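#' Cubic Ball basis functions
#'
#' Evaluates the four cubic Ball basis functions
#' \deqn{S_0(\theta) = (1-\theta)^2,\quad S_1(\theta) = 2\theta(1-\theta)^2,\quad
#'       S_2(\theta) = 2\theta^2(1-\theta),\quad S_3(\theta) = \theta^2}
#' at one or more parameter values.  The basis is an alternative to the cubic
#' Bernstein basis with the same endpoint behaviour: it is non-negative on
#' \eqn{[0, 1]}, forms a partition of unity, and is symmetric in the sense
#' \eqn{S_i(\theta) = S_{3-i}(1-\theta)}.
#'
#' @param theta numeric vector of parameter values in \eqn{[0, 1]}.  Values
#'   outside the domain raise an error rather than being clamped, so that
#'   parametrization bugs surface immediately.
#' @return a numeric matrix with one row per `theta` and columns
#'   `s0`, `s1`, `s2`, `s3`.
#' @examples
#' ball_basis(c(0, 0.5, 1))
#' rowSums(ball_basis(seq(0, 1, length.out = 11)))  # all exactly 1
#' @export
ball_basis <- function(theta) {
  theta <- check_theta(theta)
  om <- 1 - theta
  cbind(s0 = om^2,
        s1 = 2 * theta * om^2,
        s2 = 2 * theta^2 * om,
        s3 = theta^2)
}

#' Evaluate a polynomial cubic Ball curve
#'
#' Evaluates \eqn{s(\theta) = \sum_{i=0}^{3} P_i S_i(\theta)} for a control
#' polygon \eqn{P_0 \ldots P_3}.  The curve interpolates \eqn{P_0} at
#' \eqn{\theta = 0} and \eqn{P_3} at \eqn{\theta = 1}, stays inside the convex
#' hull of its controls, and collapses to the quadratic Bernstein curve when
#' \eqn{P_1 = P_2}.
#'
#' @param ctrl a 4 x 2 numeric matrix, rows \eqn{P_0 \ldots P_3}.
#' @param theta numeric vector of parameter values in \eqn{[0, 1]}.
#' @return a `length(theta)` x 2 matrix of curve points.
#' @examples
#' ctrl <- rbind(c(0, 0), c(1, 2), c(3, 2), c(4, 0))
#' eval_cubic_ball(ctrl, c(0, 0.5, 1))
#' @export
eval_cubic_ball <- function(ctrl, theta) {
  ctrl <- as_points(ctrl)
  if (nrow(ctrl) != 4L) {
    stop("`ctrl` must have exactly 4 control points", call. = FALSE)
  }
  ball_basis(theta) %*% ctrl
}
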