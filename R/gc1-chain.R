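#' GC1 linking coefficient for consecutive rational Ball segments
#'
#' Given the shared knot \eqn{f_{i+1}}, the previous segment's weight
#' \eqn{b_i} and inner coefficient \eqn{C_i}, the next segment's weight
#' \eqn{a_{i+1}} and the tangent ratio \eqn{\lambda_i > 0}, returns the
#' numerator coefficient
#' \deqn{B_{i+1} = (a_{i+1} + \lambda_i b_i) f_{i+1} - \lambda_i C_i,}
#' the unique choice making the joined segments GC1 continuous:
#' \eqn{s_{i+1}'(0) = \lambda_i s_i'(1)}.
#'
#' @param f_next shared knot point \eqn{f_{i+1}}.
#' @param a_next weight \eqn{a_{i+1}} of the next segment.
#' @param b_prev weight \eqn{b_i} of the previous segment.
#' @param lambda_prev positive tangent-magnitude ratio \eqn{\lambda_i}.
#'   Non-positive values are rejected: they would reverse the tangent
#'   direction across the join.
#' @param c_prev inner coefficient \eqn{C_i} of the previous segment.
#' @return the planar coefficient \eqn{B_{i+1}}.
#' @export
link_gc1 <- function(f_next, a_next, b_prev, lambda_prev, c_prev) {
  f_next <- as_point(f_next)
  c_prev <- as_point(c_prev)
  a_next <- check_positive(a_next, "a_next")
  b_prev <- check_positive(b_prev, "b_prev")
  lambda_prev <- check_positive(lambda_prev, "lambda_prev")
  (a_next + lambda_prev * b_prev) * f_next - lambda_prev * c_prev
}

#' Build a GC1 chain of rational cubic Ball segments
#'
#' Assembles a piecewise curve through the on-curve knots
#' \eqn{f_1, \ldots, f_n}.  The first segment takes its `B` coefficient from
#' `b_first`; every subsequent `B` is produced by [link_gc1()], so tangent
#' directions at interior knots are parallel with magnitude ratio
#' \eqn{\lambda_i} by construction.
#'
#' @param knots n x 2 matrix of on-curve points (n >= 2).
#' @param inner_controls (n-1) x 2 matrix (or list of points): the `C`
#'   numerator coefficient of each segment.
#' @param b_first planar point: `B` coefficient of the first segment.
#' @param weights (n-1) x 2 matrix with columns `a`, `b`: positive
#'   denominator weights per segment.
#' @param lambdas numeric vector of n-2 positive tangent ratios (may be
#'   `numeric(0)` when n = 2).
#' @return an object of class `gc1_chain` with components `knots`,
#'   `segments` (list of [rational_segment()]), `lambdas`, `weights`.
#' @export
build_chain <- function(knots, inner_controls, b_first, weights, lambdas) {
  knots <- as_points(knots)
  n <- nrow(knots)
  if (n < 2L) stop("need at least 2 knots", call. = FALSE)
  if (is.list(inner_controls)) {
    inner_controls <- do.call(rbind, lapply(inner_controls, as_point))
  }
  inner_controls <- as_points(inner_controls)
  weights <- as.matrix(weights)
  lambdas <- as.numeric(lambdas)
  if (nrow(inner_controls) != n - 1L || nrow(weights) != n - 1L ||
      ncol(weights) != 2L || length(lambdas) != n - 2L) {
    stop("count mismatch: need n-1 inner controls and weight pairs and ",
         "n-2 lambdas for n knots", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("segment weights must be positive", call. = FALSE)
  }
  if (length(lambdas) && (any(!is.finite(lambdas)) || any(lambdas <= 0))) {
    stop("lambdas must be positive", call. = FALSE)
  }

  segments <- vector("list", n - 1L)
  b_cur <- as_point(b_first)
  for (i in seq_len(n - 1L)) {
    segments[[i]] <- rational_segment(knots[i, ], b_cur, inner_controls[i, ],
                                      knots[i + 1L, ],
                                      weights[i, 1L], weights[i, 2L])
    if (i < n - 1L) {
      b_cur <- link_gc1(knots[i + 1L, ], weights[i + 1L, 1L],
                        weights[i, 2L], lambdas[i], inner_controls[i, ])
    }
  }
  structure(list(knots = knots, segments = segments,
                 lambdas = lambdas, weights = weights),
            class = "gc1_chain")
}

#' @export
print.gc1_chain <- function(x, ...) {
  cat(sprintf("GC1 rational cubic Ball chain: %d knots, %d segments\n",
              nrow(x$knots), length(x$segments)))
  if (length(x$lambdas)) {
    cat("  lambda:", paste(signif(x$lambdas, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate one segment of a GC1 chain
#'
#' @param chain a [build_chain()] result.
#' @param segment segment index (1-based).
#' @param theta numeric vector in \eqn{[0, 1]} (segment-local parameter).
#' @return matrix of curve points.
#' @export
eval_chain <- function(chain, segment, theta) {
  stopifnot(inherits(chain, "gc1_chain"))
  segment <- as.integer(segment)
  if (length(segment) != 1L || segment < 1L ||
      segment > length(chain$segments)) {
    stop("`segment` out of range", call. = FALSE)
  }
  eval_rational(chain$segments[[segment]], theta)
}

#' Sample a GC1 chain on a uniform per-segment grid
#'
#' @param chain a [build_chain()] result.
#' @param n_per_segment number of theta samples per segment (default 101).
#' @param dedupe drop the duplicated knot sample at each interior join
#'   (default `TRUE`).
#' @return matrix of curve points, in order along the chain.
#' @export
sample_chain <- function(chain, n_per_segment = 101L, dedupe = TRUE) {
  stopifnot(inherits(chain, "gc1_chain"))
  n_per_segment <- as.integer(n_per_segment)
  if (n_per_segment < 2L) stop("`n_per_segment` must be >= 2", call. = FALSE)
  th <- seq(0, 1, length.out = n_per_segment)
  pieces <- lapply(seq_along(chain$segments), function(i) {
    p <- eval_rational(chain$segments[[i]], th)
    if (dedupe && i > 1L) p[-1L, , drop = FALSE] else p
  })
  do.call(rbind, pieces)
}
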