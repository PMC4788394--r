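#' Triangulate a blended surface
#'
#' Converts the sampled surface grid into a triangle mesh.  Contour rows
#' shared by adjacent bands are merged, each grid quad is split into two
#' triangles, and for closed contours the grid wraps in \eqn{\psi}.
#' Triangle orientation follows the \eqn{(\psi, \theta)} parametrization,
#' so counterclockwise contours with increasing z give outward normals.
#' Degenerate (zero-area) triangles are collapsed and never emitted; a message
#' reports how many were dropped.
#'
#' @param surface a [build_surface()] result.
#' @param closed logical: wrap the mesh in \eqn{\psi}; defaults to the
#'   surface's own flag.
#' @return an object of class `triangle_mesh` with components `vertices`
#'   (V x 3) and `triangles` (T x 3, 1-based indices).
#' @export
surface_to_mesh <- function(surface, closed = surface$closed) {
  stopifnot(inherits(surface, "blended_surface"))
  bands <- surface$bands
  tdim <- dim(bands[[1L]])
  tn <- tdim[1L]; m <- tdim[2L]
  if (tn < 2L || m < 2L) stop("grid must be at least 2 x 2", call. = FALSE)

  # global rows: band 1 contributes all theta rows, later bands drop their
  # first row (identical to the previous band's last row by construction)
  rows <- list(bands[[1L]])
  if (length(bands) > 1L) {
    for (i in 2:length(bands)) {
      rows[[i]] <- bands[[i]][-1L, , , drop = FALSE]
    }
  }
  grid <- do.call(abind_rows3, rows)
  nrows <- dim(grid)[1L]
  verts <- matrix(NA_real_, nrows * m, 3L)
  for (k in 1:3) verts[, k] <- as.vector(t(grid[, , k]))
  vid <- function(r, j) (r - 1L) * m + j  # j in 1..m

  ncell_psi <- if (closed) m else m - 1L
  tris <- matrix(NA_integer_, 2L * (nrows - 1L) * ncell_psi, 3L)
  tcount <- 0L
  dropped <- 0L
  tri_area2 <- function(a, b, c) {
    u <- verts[b, ] - verts[a, ]
    w <- verts[c, ] - verts[a, ]
    cr <- c(u[2L] * w[3L] - u[3L] * w[2L],
            u[3L] * w[1L] - u[1L] * w[3L],
            u[1L] * w[2L] - u[2L] * w[1L])
    sum(cr * cr)
  }
  for (r in seq_len(nrows - 1L)) {
    for (j in seq_len(ncell_psi)) {
      j2 <- if (j == m) 1L else j + 1L
      v00 <- vid(r, j); v01 <- vid(r, j2)
      v10 <- vid(r + 1L, j); v11 <- vid(r + 1L, j2)
      for (tri in list(c(v00, v01, v11), c(v00, v11, v10))) {
        if (tri_area2(tri[1L], tri[2L], tri[3L]) > 1e-24) {
          tcount <- tcount + 1L
          tris[tcount, ] <- tri
        } else {
          dropped <- dropped + 1L
        }
      }
    }
  }
  if (dropped > 0L) {
    message("surface_to_mesh: dropped ", dropped, " degenerate triangle(s)")
  }
  structure(list(vertices = verts,
                 triangles = tris[seq_len(tcount), , drop = FALSE]),
            class = "triangle_mesh")
}

# bind 3D arrays along the first dimension (rows of the surface grid)
abind_rows3 <- function(...) {
  arrs <- list(...)
  n1 <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(n1, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Write a triangle mesh as binary STL
#'
#' Standard little-endian binary STL: an 80-byte header, a uint32 triangle
#' count, then 50 bytes per facet (normal, three vertices, attribute).
#'
#' @param mesh a [surface_to_mesh()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "cranioball surface"))[1:80]
  writeBin(header, con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (t in seq_len(nt)) {
    tri <- mesh$triangles[t, ]
    a <- v[tri[1L], ]; b <- v[tri[2L], ]; cc <- v[tri[3L], ]
    u <- b - a; w <- cc - a
    nrm <- c(u[2L] * w[3L] - u[3L] * w[2L],
             u[3L] * w[1L] - u[1L] * w[3L],
             u[1L] * w[2L] - u[2L] * w[1L])
    nl <- vnorm(nrm)
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, a, b, cc)), con, size = 4L,
             endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' Plain-text `v`/`f` records with 1-based indices.
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
               mesh$vertices[, 2L], mesh$vertices[, 3L])
  f <- sprintf("f %d %d %d", mesh$triangles[, 1L],
               mesh$triangles[, 2L], mesh$triangles[, 3L])
  writeLines(c("# cranioball surface", v, f), path)
  invisible(path)
}
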