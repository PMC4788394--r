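#' Rational cubic Ball curve segment
#'
#' Constructs one rational cubic Ball segment
#' \deqn{s(\theta) = P(\theta) / Q(\theta)} with
#' \deqn{P(\theta) = A(1-\theta)^2 + B(1-\theta)^2\theta + C(1-\theta)\theta^2 + D\theta^2}
#' \deqn{Q(\theta) = (1-\theta)^2 + a(1-\theta)^2\theta + b(1-\theta)\theta^2 + \theta^2.}
#' `B` and `C` are *weighted numerator coefficients*, not geometric control
#' points: the off-curve control point pulled toward by the weight `a` is
#' `B/a` (resp. `C/b`).  Positive weights guarantee \eqn{Q(\theta) > 0} on
#' \eqn{[0, 1]}, and the segment interpolates `a_pt` at \eqn{\theta = 0} and
#' `d_pt` at \eqn{\theta = 1}.
#'
#' @param a_pt,b_pt,c_pt,d_pt planar points (length-2 numeric): the numerator
#'   coefficients \eqn{A, B, C, D}.
#' @param a_w,b_w positive denominator weights \eqn{a, b}.  Increasing `a_w`
#'   pulls the curve toward `b_pt/a_w`; increasing `b_w` pulls it toward
#'   `c_pt/b_w`.
#' @return an object of class `rational_segment`.
#' @seealso [eval_rational()], [endpoint_derivatives()], [build_chain()]
#' @export
rational_segment <- function(a_pt, b_pt, c_pt, d_pt, a_w = 1, b_w = 1) {
  seg <- list(a_pt = as_point(a_pt), b_pt = as_point(b_pt),
              c_pt = as_point(c_pt), d_pt = as_point(d_pt),
              a_w = check_positive(a_w, "a_w"),
              b_w = check_positive(b_w, "b_w"))
  class(seg) <- "rational_segment"
  seg
}

#' @export
print.rational_segment <- function(x, ...) {
  cat("rational cubic Ball segment\n")
  cat(sprintf("  A = (%.4g, %.4g)   D = (%.4g, %.4g)\n",
              x$a_pt[1], x$a_pt[2], x$d_pt[1], x$d_pt[2]))
  cat(sprintf("  B = (%.4g, %.4g)   C = (%.4g, %.4g)\n",
              x$b_pt[1], x$b_pt[2], x$c_pt[1], x$c_pt[2]))
  cat(sprintf("  weights a = %.4g, b = %.4g\n", x$a_w, x$b_w))
  invisible(x)
}

#' Evaluate a rational cubic Ball segment
#'
#' @param seg a [rational_segment()].
#' @param theta numeric vector of parameter values in \eqn{[0, 1]}.
#' @return a `length(theta)` x 2 matrix of curve points \eqn{P(\theta)/Q(\theta)}.
#' @examples
#' seg <- rational_segment(c(0, 0), c(1, 0), c(1, 0), c(0, 0))
#' eval_rational(seg, 0.5)  # (1/3, 0)
#' @export
eval_rational <- function(seg, theta) {
  stopifnot(inherits(seg, "rational_segment"))
  theta <- check_theta(theta)
  om <- 1 - theta
  n0 <- om^2
  n1 <- om^2 * theta
  n2 <- om * theta^2
  n3 <- theta^2
  q <- n0 + seg$a_w * n1 + seg$b_w * n2 + n3
  if (any(q <= 0)) {
    # cannot happen for positive weights; guards corrupted objects
    stop("internal error: rational denominator Q(theta) <= 0", call. = FALSE)
  }
  p <- outer(n0, seg$a_pt) + outer(n1, seg$b_pt) +
    outer(n2, seg$c_pt) + outer(n3, seg$d_pt)
  out <- p / q
  colnames(out) <- c("x", "y")
  out
}

#' Endpoint derivatives of a rational segment
#'
#' Closed forms of the parametric derivative at the segment ends,
#' \eqn{s'(0) = B - aA} and \eqn{s'(1) = bD - C}, obtained from the quotient
#' rule using \eqn{Q(0) = Q(1) = 1}.  These are what the GC1 linking
#' condition \eqn{s_{i+1}'(0) = \lambda_i s_i'(1)} acts on.
#'
#' @param seg a [rational_segment()].
#' @return a list with components `start` and `end`, each a planar vector.
#' @export
endpoint_derivatives <- function(seg) {
  stopifnot(inherits(seg, "rational_segment"))
  list(start = seg$b_pt - seg$a_w * seg$a_pt,
       end   = seg$b_w * seg$d_pt - seg$c_pt)
}
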