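# shared fixtures, all generated in code

# dense point chain along a regular n-gon perimeter (unit spacing), closed
ngon_chain <- function(n, r = 60) {
  v <- cbind(r * cos(2 * pi * (0:n) / n), r * sin(2 * pi * (0:n) / n))
  out <- NULL
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, round(len)))[-1L]
    out <- rbind(out, cbind(a[1L] + t * (b[1L] - a[1L]),
                            a[2L] + t * (b[2L] - a[2L])))
  }
  structure(out, closed = TRUE)
}

# m points on a circle (no duplicate closure point)
circle_points <- function(m, r = 50, cx = 0, cy = 0, phase = 0) {
  t <- 2 * pi * (seq_len(m) - 1) / m + phase
  cbind(cx + r * cos(t), cy + r * sin(t))
}

# brute-force morphological boundary: per-pixel erosion by definition
brute_force_boundary <- function(mask, elem = "box") {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (elem == "box") {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  } else {
    rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (mask[r, c] == 0) next
      eroded <- TRUE
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc || mask[rr, cc] == 0) {
          eroded <- FALSE
          break
        }
      }
      if (!eroded) out[r, c] <- 1L
    }
  }
  out
}

# is a point inside the convex hull of a point set (within tol)?
in_convex_hull <- function(pt, pts, tol = 1e-9) {
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]  # counterclockwise
  nh <- nrow(hp)
  if (nh == 1L) return(sqrt(sum((pt - hp[1L, ])^2)) <= tol)
  if (nh == 2L) {
    d <- hp[2L, ] - hp[1L, ]
    w <- pt - hp[1L, ]
    cross <- d[1L] * w[2L] - d[2L] * w[1L]
    t <- sum(w * d) / sum(d * d)
    return(abs(cross) / sqrt(sum(d * d)) <= tol && t >= -tol && t <= 1 + tol)
  }
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    # chull is clockwise in R; inside means cross <= tol for cw order
    cross <- e[1L] * (pt[2L] - a[2L]) - e[2L] * (pt[1L] - a[1L])
    if (cross > tol * max(1, sqrt(sum(e * e)))) return(FALSE)
  }
  TRUE
}

# second-order one-sided finite differences of a rational segment
fd_deriv_start <- function(seg, h = 1e-6) {
  (-3 * eval_rational(seg, 0) + 4 * eval_rational(seg, h) -
     eval_rational(seg, 2 * h)) / (2 * h)
}
fd_deriv_end <- function(seg, h = 1e-6) {
  (3 * eval_rational(seg, 1) - 4 * eval_rational(seg, 1 - h) +
     eval_rational(seg, 1 - 2 * h)) / (2 * h)
}

# random GC1 chain with known parameters
random_chain <- function(n_knots = 4L) {
  knots <- cbind(cumsum(runif(n_knots, 0.5, 2)), runif(n_knots, -1, 1))
  inner <- knots[-1L, , drop = FALSE] + matrix(runif(2L * (n_knots - 1L),
                                                     -1, 1),
                                               ncol = 2L)
  weights <- cbind(runif(n_knots - 1L, 0.5, 3), runif(n_knots - 1L, 0.5, 3))
  lambdas <- runif(n_knots - 2L, 0.5, 2)
  b_first <- knots[1L, ] + runif(2L, -1, 1)
  build_chain(knots, inner, b_first, weights, lambdas)
}

# moderately curved GC1 chain, the regime of slice-boundary arcs
tame_chain <- function(n_knots = 3L) {
  n <- n_knots
  knots <- cbind(cumsum(runif(n, 1.5, 2.5)), runif(n, -0.5, 0.5))
  mid <- (knots[-n, , drop = FALSE] + knots[-1L, , drop = FALSE]) / 2
  inner <- mid + matrix(runif(2L * (n - 1L), -0.4, 0.4), ncol = 2L)
  weights <- cbind(runif(n - 1L, 0.8, 1.5), runif(n - 1L, 0.8, 1.5))
  lambdas <- runif(n - 2L, 0.7, 1.4)
  b_first <- knots[1L, ] + (knots[2L, ] - knots[1L, ]) * 0.3 +
    runif(2L, -0.3, 0.3)
  build_chain(knots, inner, b_first, weights, lambdas)
}

# vertices of a binary STL written by write_stl()
read_stl_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nt <- readBin(con, "integer", 1L, 4L, endian = "little")
  v <- matrix(NA_real_, 3L * nt, 3L)
  for (t in seq_len(nt)) {
    dat <- readBin(con, "numeric", 12L, 4L, endian = "little")
    readBin(con, "raw", 2L)
    v[(3L * t - 2L):(3L * t), ] <- matrix(dat[4:12], 3L, 3L, byrow = TRUE)
  }
  v
}

# directed Hausdorff distance from points a to points b (both n x 2)
hausdorff_to <- function(a, b) {
  max(vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2))
  }, numeric(1)))
}
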