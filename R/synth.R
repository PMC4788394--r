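#' Specification of a synthetic skull-slice phantom
#'
#' Describes a stack of annular (skull-like) slices with analytic geometry:
#' an outer boundary at radius
#' \eqn{\rho_i(\psi) = r_{out}(i)\,(1 + a \cos(2\pi h \psi))} and an inner
#' boundary offset inward by `thickness`, optionally with an angular
#' "fracture" gap removed from a range of slices.  Everything downstream of
#' the generator (masks, contours, gap endpoints) derives exactly from this
#' spec, so it provides ground truth for every pipeline stage.
#'
#' @param n_slices number of slices (>= 2).
#' @param size image side length in pixels (square slices).
#' @param r_out outer base radius in mm: a scalar (cylinder), a vector of
#'   per-slice radii (e.g. linear for a cone), or a function of the slice
#'   index.
#' @param thickness annulus thickness in mm (> 0).
#' @param center annulus centre in mm; default the image centre.
#' @param perturb_amplitude relative radial perturbation amplitude `a`
#'   (default 0: perfect circles).
#' @param perturb_harmonic integer harmonic `h` of the perturbation.
#' @param fracture_angles numeric `c(alpha1, alpha2)` in radians with
#'   `0 <= alpha1 < alpha2 < 2*pi`, or `NULL` for no fracture.
#' @param fracture_slices integer indices of slices carrying the gap
#'   (default: all slices, when `fracture_angles` is given).
#' @param dz slice spacing in mm (> 0).
#' @param z_start height of the first slice in mm.
#' @param spacing pixel spacing in mm/px (default 0.5).
#' @param seed integer seed recorded with the spec (the phantom itself is
#'   analytic and fully deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 8L, size = 256L, r_out = 25,
                         thickness = 5, center = NULL,
                         perturb_amplitude = 0, perturb_harmonic = 3L,
                         fracture_angles = NULL, fracture_slices = NULL,
                         dz = 1, z_start = 0, spacing = 0.5, seed = 1L) {
  n_slices <- as.integer(n_slices)
  size <- as.integer(size)
  if (n_slices < 2L) stop("`n_slices` must be >= 2", call. = FALSE)
  if (size < 16L) stop("`size` too small", call. = FALSE)
  thickness <- check_positive(thickness, "thickness")
  dz <- check_positive(dz, "dz")
  spacing <- check_positive(spacing, "spacing")
  r <- if (is.function(r_out)) {
    vapply(seq_len(n_slices), r_out, numeric(1))
  } else if (length(r_out) == 1L) {
    rep(as.numeric(r_out), n_slices)
  } else if (length(r_out) == n_slices) {
    as.numeric(r_out)
  } else {
    stop("`r_out` must be scalar, length n_slices, or a function",
         call. = FALSE)
  }
  if (any(!is.finite(r)) || any(r <= thickness)) {
    stop("outer radii must be finite and exceed `thickness`", call. = FALSE)
  }
  if (is.null(center)) center <- rep(size / 2 * spacing, 2L)
  center <- as_point(center)
  if (perturb_amplitude < 0 || perturb_amplitude >= 0.5) {
    stop("`perturb_amplitude` must be in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(fracture_angles)) {
    fracture_angles <- as.numeric(fracture_angles)
    if (length(fracture_angles) != 2L ||
        fracture_angles[1L] < 0 ||
        fracture_angles[1L] >= fracture_angles[2L] ||
        fracture_angles[2L] >= 2 * pi) {
      stop("`fracture_angles` must satisfy 0 <= a1 < a2 < 2*pi",
           call. = FALSE)
    }
    if (is.null(fracture_slices)) fracture_slices <- seq_len(n_slices)
    fracture_slices <- as.integer(fracture_slices)
    if (any(fracture_slices < 1L | fracture_slices > n_slices)) {
      stop("`fracture_slices` out of range", call. = FALSE)
    }
  } else {
    fracture_slices <- integer(0)
  }
  structure(list(n_slices = n_slices, size = size, r_out = r,
                 thickness = thickness, center = center,
                 perturb_amplitude = perturb_amplitude,
                 perturb_harmonic = as.integer(perturb_harmonic),
                 fracture_angles = fracture_angles,
                 fracture_slices = fracture_slices,
                 dz = dz, z_start = z_start, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# outer radius at slice i and polar angle phi (radians)
phantom_radius <- function(spec, i, phi) {
  spec$r_out[i] * (1 + spec$perturb_amplitude *
                     cos(spec$perturb_harmonic * phi))
}

#' Analytic contour stack and ground truth of a phantom
#'
#' Samples the phantom's outer (and inner) contours analytically and
#' returns them with the exact fracture-gap endpoint coordinates.  The
#' contour samples use \eqn{\psi_j = (j-1)/m}, i.e. points
#' \eqn{center + \rho_i(\psi)\,(\cos 2\pi\psi, \sin 2\pi\psi)}, so the
#' stack is aligned by construction.
#'
#' @param spec a [phantom_spec()].
#' @param m samples per contour (default 200).
#' @return a list with components `stack` (a [stack_to_3d()] contour stack
#'   of the *unfractured* outer contours), `inner` (n x m x 2 array of
#'   inner contours), `gap_endpoints` (list per fractured slice:
#'   `outer`/`inner` 2 x 2 matrices at angles alpha1, alpha2) and `spec`.
#' @export
make_contour_stack <- function(spec, m = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- as.integer(m)
  psi <- (seq_len(m) - 1) / m
  phi <- 2 * pi * psi
  n <- spec$n_slices
  outer_arr <- array(NA_real_, c(n, m, 2L))
  inner_arr <- array(NA_real_, c(n, m, 2L))
  for (i in seq_len(n)) {
    rho <- phantom_radius(spec, i, phi)
    outer_arr[i, , ] <- cbind(spec$center[1L] + rho * cos(phi),
                              spec$center[2L] + rho * sin(phi))
    rin <- rho - spec$thickness
    inner_arr[i, , ] <- cbind(spec$center[1L] + rin * cos(phi),
                              spec$center[2L] + rin * sin(phi))
  }
  gaps <- NULL
  if (length(spec$fracture_slices)) {
    gaps <- lapply(spec$fracture_slices, function(i) {
      ang <- spec$fracture_angles
      ro <- phantom_radius(spec, i, ang)
      ri <- ro - spec$thickness
      list(slice = i,
           outer = cbind(x = spec$center[1L] + ro * cos(ang),
                         y = spec$center[2L] + ro * sin(ang)),
           inner = cbind(x = spec$center[1L] + ri * cos(ang),
                         y = spec$center[2L] + ri * sin(ang)))
    })
  }
  list(stack = stack_to_3d(outer_arr, z_start = spec$z_start, dz = spec$dz,
                           closed = TRUE),
       inner = inner_arr, gap_endpoints = gaps, spec = spec)
}

#' Rasterize phantom slices to grayscale images
#'
#' Renders each slice as a binary-valued grayscale image (annulus at
#' intensity 255 on background 0, no anti-aliasing): a pixel is foreground
#' iff its centre lies between the analytic inner and outer radii at its
#' polar angle, and outside the fracture interval on fractured slices.
#' Masks therefore rasterize exactly from the analytic contours.
#'
#' @param spec a [phantom_spec()].
#' @return list of `size` x `size` numeric matrices (values 0/255), one per
#'   slice, rows top-down as in image files.
#' @export
rasterize_slices <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size
  # pixel-centre coordinates in mm, standard orientation (y up)
  xs <- (seq_len(size) - 1) * spec$spacing
  ys <- (size - seq_len(size)) * spec$spacing  # per row
  dx <- matrix(xs, size, size, byrow = TRUE) - spec$center[1L]
  dy <- matrix(ys, size, size) - spec$center[2L]
  r <- sqrt(dx * dx + dy * dy)
  phi <- atan2(dy, dx)
  phi[phi < 0] <- phi[phi < 0] + 2 * pi
  if (max(spec$r_out) * (1 + spec$perturb_amplitude) >
      min(spec$center, size * spec$spacing - spec$center)) {
    stop("phantom contour exceeds image bounds", call. = FALSE)
  }
  lapply(seq_len(spec$n_slices), function(i) {
    ro <- phantom_radius(spec, i, phi)
    fg <- r <= ro & r >= ro - spec$thickness
    if (i %in% spec$fracture_slices) {
      ang <- spec$fracture_angles
      fg <- fg & !(phi >= ang[1L] & phi <= ang[2L])
    }
    matrix(as.numeric(fg) * 255, size, size)
  })
}

#' Distance from a reconstruction to the analytic phantom surface
#'
#' Measures, for every vertex of a reconstructed mesh (or any 3D point
#' set), the absolute radial distance to the *unfractured* analytic outer
#' surface of the phantom, with per-slice radii interpolated linearly in z.
#' Used to quantify end-to-end reconstruction error in mm.
#'
#' @param spec a [phantom_spec()].
#' @param reconstruction a `triangle_mesh`, or a V x 3 matrix of points.
#' @return list with `max`, `mean` (mm) and `n` vertices measured.
#' @export
end_to_end_truth_error <- function(spec, reconstruction) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- if (inherits(reconstruction, "triangle_mesh")) {
    reconstruction$vertices
  } else {
    as.matrix(reconstruction)
  }
  if (!is.matrix(v) || ncol(v) != 3L || nrow(v) == 0L) {
    stop("`reconstruction` must be a triangle_mesh or non-empty V x 3 matrix",
         call. = FALSE)
  }
  t_sl <- (v[, 3L] - spec$z_start) / spec$dz + 1
  t_sl <- pmin(pmax(t_sl, 1), spec$n_slices)
  i0 <- pmin(floor(t_sl), spec$n_slices - 1L)
  w <- t_sl - i0
  r_base <- (1 - w) * spec$r_out[i0] + w * spec$r_out[i0 + 1L]
  dx <- v[, 1L] - spec$center[1L]
  dy <- v[, 2L] - spec$center[2L]
  phi <- atan2(dy, dx)
  rho <- r_base * (1 + spec$perturb_amplitude *
                     cos(spec$perturb_harmonic * phi))
  d <- abs(sqrt(dx * dx + dy * dy) - rho)
  list(max = max(d), mean = mean(d), n = nrow(v))
}

#' Write phantom slices and truth to a directory
#'
#' Writes the rasterized slice stack as numbered PNG files, the analytic
#' truth contours and gap endpoints as JSON, and the spec as a config-style
#' text file, so a phantom directory is a complete self-describing input
#' for [run_pipeline()].
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param m contour samples for the truth JSON.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(spec, dir, m = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- rasterize_slices(spec)
  for (i in seq_along(imgs)) {
    png::writePNG(imgs[[i]] / 255,
                  file.path(dir, sprintf("slice_%03d.png", i)))
  }
  truth <- make_contour_stack(spec, m)
  jsonlite::write_json(
    list(units = "mm",
         z = truth$stack$z,
         outer = lapply(seq_len(spec$n_slices),
                        function(i) unname(truth$stack$points[i, , ])),
         inner = lapply(seq_len(spec$n_slices),
                        function(i) unname(truth$inner[i, , ])),
         gap_endpoints = truth$gap_endpoints),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_config(phantom_spec_config(spec), file.path(dir, "phantom.ini"))
  invisible(dir)
}

# flatten a phantom_spec into config sections for write_config()
phantom_spec_config <- function(spec) {
  ph <- list(n_slices = spec$n_slices, size = spec$size,
             thickness = spec$thickness,
             r_out = paste(spec$r_out, collapse = ","),
             center = paste(spec$center, collapse = ","),
             perturb_amplitude = spec$perturb_amplitude,
             perturb_harmonic = spec$perturb_harmonic,
             dz = spec$dz, z_start = spec$z_start,
             spacing = spec$spacing, seed = spec$seed)
  if (!is.null(spec$fracture_angles)) {
    ph$fracture_angles <- paste(spec$fracture_angles, collapse = ",")
    ph$fracture_slices <- paste(spec$fracture_slices, collapse = ",")
  }
  list(phantom = ph)
}
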