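#' Resample raw contours to aligned sample matrices
#'
#' Each contour is resampled at `m` uniform arc-length fractions so that the
#' sample index plays the role of the common surface parameter \eqn{\psi}.
#' For closed contours the polygon is treated as periodic and, from the
#' second contour on, the cyclic shift (exhaustive over all m shifts)
#' minimizing the sum of squared distances to the previous contour's samples
#' is applied, so corresponding samples line up vertically.  Open arcs are
#' aligned endpoint-to-endpoint (sample 1 and sample m are the given
#' endpoints).
#'
#' @param contours list of n_i x 2 point matrices (ordered; closed contours
#'   need >= 3 points, open arcs >= 2).
#' @param m number of samples per contour.
#' @param closed logical: treat contours as closed loops (default `TRUE`).
#' @return a `length(contours)` x m x 2 array of aligned samples.
#' @export
resample_aligned <- function(contours, m, closed = TRUE) {
  if (!is.list(contours) || length(contours) < 1L) {
    stop("`contours` must be a non-empty list", call. = FALSE)
  }
  m <- as.integer(m)
  if (m < 3L) stop("`m` must be >= 3", call. = FALSE)
  n <- length(contours)
  out <- array(NA_real_, c(n, m, 2L))
  fracs <- if (closed) (seq_len(m) - 1) / m else seq(0, 1, length.out = m)
  for (i in seq_len(n)) {
    pts <- as_points(contours[[i]], sprintf("contours[[%d]]", i))
    if (closed && nrow(pts) >= 2L &&
        vnorm(pts[1L, ] - pts[nrow(pts), ]) == 0) {
      pts <- pts[-nrow(pts), , drop = FALSE]  # drop explicit closure
    }
    if (nrow(pts) < (if (closed) 3L else 2L)) {
      stop("contour ", i, " has too few points", call. = FALSE)
    }
    poly <- if (closed) rbind(pts, pts[1L, ]) else pts
    seglen <- row_norms(diff(poly))
    total <- sum(seglen)
    if (total == 0) stop("contour ", i, " has zero length", call. = FALSE)
    cum <- c(0, cumsum(seglen)) / total
    sx <- stats::approx(cum, poly[, 1L], xout = fracs, ties = "ordered")$y
    sy <- stats::approx(cum, poly[, 2L], xout = fracs, ties = "ordered")$y
    samp <- cbind(sx, sy)
    if (closed && i > 1L) {
      prev <- out[i - 1L, , , drop = TRUE]
      costs <- vapply(0:(m - 1L), function(s) {
        idx <- ((seq_len(m) - 1L + s) %% m) + 1L
        sum((samp[idx, ] - prev)^2)
      }, numeric(1))
      s <- which.min(costs) - 1L
      samp <- samp[((seq_len(m) - 1L + s) %% m) + 1L, , drop = FALSE]
    }
    out[i, , ] <- samp
  }
  out
}

#' Stack 2D contours into 3D at equidistant heights
#'
#' Assigns contour i the height \eqn{z^i = z_{start} + (i-1)\Delta z}, the
#' equidistant stacking used when lifting per-slice CT contours into 3D.
#'
#' @param curves aligned samples: an n x m x 2 array (see
#'   [resample_aligned()]) or a list of n matrices of identical dimension
#'   m x 2.
#' @param z_start height of the first contour (mm).
#' @param dz positive slice spacing (mm).
#' @param closed logical: contours are closed loops.
#' @return an object of class `contour_stack` with components `points`
#'   (n x m x 2), `z` (length n), `closed`.
#' @export
stack_to_3d <- function(curves, z_start = 0, dz = 1, closed = TRUE) {
  if (is.list(curves)) {
    mats <- lapply(curves, as_points)
    ms <- vapply(mats, nrow, integer(1))
    if (length(unique(ms)) != 1L) {
      stop("all contours must share the same number of samples",
           call. = FALSE)
    }
    arr <- array(NA_real_, c(length(mats), ms[1L], 2L))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    curves <- arr
  }
  if (!is.array(curves) || length(dim(curves)) != 3L || dim(curves)[3L] != 2L) {
    stop("`curves` must be an n x m x 2 array or list of m x 2 matrices",
         call. = FALSE)
  }
  n <- dim(curves)[1L]
  if (n < 2L) stop("need at least 2 contours to stack", call. = FALSE)
  dz <- check_positive(dz, "dz")
  structure(list(points = curves,
                 z = z_start + (seq_len(n) - 1) * dz,
                 closed = isTRUE(closed)),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("contour stack: %d contours x %d samples, z in [%g, %g]%s\n",
              dim(x$points)[1L], dim(x$points)[2L], min(x$z), max(x$z),
              if (x$closed) " (closed)" else " (open arcs)"))
  invisible(x)
}

#' Inter-contour tangent field
#'
#' For each contour i and sample \eqn{\psi_j}, the planar tangent
#' \deqn{v^i(\psi) = \frac{|D_1| D_2 + |D_2| D_1}
#'       {|D_1|(z^i - z^{i-1}) + |D_2|(z^{i+1} - z^i)}}
#' with forward difference \eqn{D_1 = C^{i+1} - C^i} and backward difference
#' \eqn{D_2 = C^i - C^{i-1}}; \eqn{(v^i, 1)} is then tangent to the lofted
#' surface at \eqn{(C^i(\psi), z^i)}.  Degenerate cases follow the scheme's
#' rules: if all three corresponding points coincide \eqn{v = (0, 0)}, and
#' if \eqn{D_1, D_2} are antiparallel multiples of one unit vector
#' (\eqn{\lambda\mu < 0}) the numerator cancels and \eqn{v = 0}.  The first
#' and last contours, which have only one neighbour, use the one-sided
#' slopes \eqn{v^1 = (C^2 - C^1)/(z^2 - z^1)} and symmetrically at i = n.
#'
#' @param stack a [stack_to_3d()] contour stack (n >= 2).
#' @return an n x m x 2 array of tangent vectors.
#' @export
tangent_field <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  p <- stack$points
  z <- stack$z
  n <- dim(p)[1L]; m <- dim(p)[2L]
  v <- array(0, c(n, m, 2L))
  # one-sided boundary rules
  v[1L, , ] <- (matrix(p[2L, , ], ncol = 2L) - matrix(p[1L, , ], ncol = 2L)) /
    (z[2L] - z[1L])
  v[n, , ] <- (matrix(p[n, , ], ncol = 2L) -
                 matrix(p[n - 1L, , ], ncol = 2L)) / (z[n] - z[n - 1L])
  if (n >= 3L) {
    sl <- function(i) matrix(p[i, , ], ncol = 2L)
    for (i in 2:(n - 1L)) {
      d1 <- sl(i + 1L) - sl(i)
      d2 <- sl(i) - sl(i - 1L)
      n1 <- sqrt(rowSums(d1 * d1))
      n2 <- sqrt(rowSums(d2 * d2))
      num <- n1 * d2 + n2 * d1
      den <- n1 * (z[i] - z[i - 1L]) + n2 * (z[i + 1L] - z[i])
      vi <- matrix(0, m, 2L)
      ok <- den > 0
      vi[ok, ] <- num[ok, , drop = FALSE] / den[ok]
      # den == 0 only when D1 = D2 = 0 (coincident points): v stays (0, 0)
      v[i, , ] <- vi
    }
  }
  v
}

# closed form of the tangent when the three corresponding points are
# collinear in a vertical plane: D1 = lambda v*, D2 = mu v*, lambda*mu > 0.
# Used as an independent consistency check against tangent_field().
tangent_collinear_closed_form <- function(lambda, mu, dz_minus, dz_plus,
                                          v_star) {
  if (lambda * mu < 0) return(c(0, 0))
  (2 * lambda * mu / (lambda * dz_minus + mu * dz_plus)) * as_point(v_star)
}

#' Blend one band between two consecutive contours
#'
#' Evaluates the cubic Ball interpolant between the aligned contours
#' \eqn{C^i} and \eqn{C^{i+1}} with prescribed inter-slice tangents.  The
#' default `"hermite"` mode uses the coefficients
#' \eqn{h_0 = C^i}, \eqn{h_1 = C^i + (\Delta z/2) v^i},
#' \eqn{h_2 = C^{i+1} - (\Delta z/2) v^{i+1}}, \eqn{h_3 = C^{i+1}}: the
#' unique cubic Ball form whose \eqn{\theta}-derivative at \eqn{\theta = 0, 1}
#' equals \eqn{\Delta z\, v}, which makes \eqn{(v, 1)} the surface tangent
#' at each contour and reproduces cylinders and cones exactly.  `"literal"`
#' mode instead combines \eqn{C^i S_0 + \Delta z\, v^i S_1 + v^{i+1} S_2 +
#' C^{i+1} S_3} (position terms absent from the inner coefficients), kept
#' for comparison experiments; it does not reproduce a cylinder.
#'
#' @param ci,ci1 m x 2 matrices of aligned contour samples at heights
#'   `zi` < `zi1`.
#' @param vi,vi1 m x 2 matrices of tangents at the two contours.
#' @param zi,zi1 contour heights (mm), `zi1 > zi`.
#' @param theta numeric vector of blend parameters in \eqn{[0, 1]}.
#' @param mode `"hermite"` (default) or `"literal"`.
#' @return a `length(theta)` x m x 2 array of planar blend values.
#' @export
blend_band <- function(ci, ci1, vi, vi1, zi, zi1,
                       theta = seq(0, 1, length.out = 9L),
                       mode = c("hermite", "literal")) {
  mode <- match.arg(mode)
  ci <- as_points(ci); ci1 <- as_points(ci1)
  vi <- as_points(vi); vi1 <- as_points(vi1)
  m <- nrow(ci)
  if (nrow(ci1) != m || nrow(vi) != m || nrow(vi1) != m) {
    stop("grid misalignment: contour and tangent arrays differ in length",
         call. = FALSE)
  }
  if (!(zi1 > zi)) stop("`zi1` must exceed `zi`", call. = FALSE)
  theta <- check_theta(theta)
  dz <- zi1 - zi
  s <- ball_basis(theta)
  if (mode == "hermite") {
    h0 <- ci
    h1 <- ci + (dz / 2) * vi
    h2 <- ci1 - (dz / 2) * vi1
    h3 <- ci1
  } else {
    h0 <- ci
    h1 <- dz * vi
    h2 <- vi1
    h3 <- ci1
  }
  out <- array(NA_real_, c(length(theta), m, 2L))
  for (k in 1:2) {
    out[, , k] <- s[, 1L] %o% h0[, k] + s[, 2L] %o% h1[, k] +
      s[, 3L] %o% h2[, k] + s[, 4L] %o% h3[, k]
  }
  # exact endpoint interpolation regardless of rounding
  for (i in which(theta == 0)) out[i, , ] <- ci
  for (i in which(theta == 1)) out[i, , ] <- ci1
  out
}

#' Build the blended surface over a contour stack
#'
#' Applies [blend_band()] between every pair of consecutive contours and
#' attaches the linear height \eqn{(1-\theta) z^i + \theta z^{i+1}}, giving
#' the full lofted surface.  Adjacent bands share their contour row exactly.
#'
#' @param stack a [stack_to_3d()] contour stack.
#' @param theta_samples number of \eqn{\theta} samples per band (>= 2).
#' @param mode blend mode passed to [blend_band()].
#' @return an object of class `blended_surface`: list of per-band
#'   `theta_samples` x m x 3 arrays (`bands`), plus `z`, `theta`, `closed`.
#' @export
build_surface <- function(stack, theta_samples = 9L,
                          mode = c("hermite", "literal")) {
  stopifnot(inherits(stack, "contour_stack"))
  mode <- match.arg(mode)
  theta_samples <- as.integer(theta_samples)
  if (theta_samples < 2L) stop("`theta_samples` must be >= 2", call. = FALSE)
  v <- tangent_field(stack)
  p <- stack$points
  z <- stack$z
  n <- dim(p)[1L]; m <- dim(p)[2L]
  th <- seq(0, 1, length.out = theta_samples)
  bands <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    b <- blend_band(p[i, , ], p[i + 1L, , ], v[i, , ], v[i + 1L, , ],
                    z[i], z[i + 1L], th, mode)
    band <- array(NA_real_, c(theta_samples, m, 3L))
    band[, , 1:2] <- b
    band[, , 3L] <- matrix((1 - th) * z[i] + th * z[i + 1L],
                           theta_samples, m)
    bands[[i]] <- band
  }
  structure(list(bands = bands, z = z, theta = th, closed = stack$closed),
            class = "blended_surface")
}

#' @export
print.blended_surface <- function(x, ...) {
  d <- dim(x$bands[[1L]])
  cat(sprintf("blended surface: %d band(s), grid %d theta x %d psi\n",
              length(x$bands), d[1L], d[2L]))
  invisible(x)
}
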