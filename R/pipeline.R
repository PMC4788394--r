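#' Pipeline configuration
#'
#' Bundles all settings of the slice-to-surface reconstruction pipeline:
#' input location and format, binarization, corner detection, GA fitting,
#' blending and meshing.
#'
#' @param input input path: a directory of numbered PNG/TIFF slices
#'   (`format = "png"`) or a contours CSV written by
#'   [write_contours_csv()] (`format = "contours"`).
#' @param output_dir directory for all artifacts (created if needed).
#' @param format `"png"` or `"contours"`.
#' @param threshold optional explicit binarization threshold (default Otsu).
#' @param corner_k,corner_cos,nms_radius corner-detector settings, see
#'   [detect_corners()].
#' @param ga a [ga_config()]; its seed fixes all stochastic steps.  The
#'   pipeline default drives each segment to NMSE 1e-6 (or 60 generations)
#'   for sub-pixel contours; the summary still reports each slice against
#'   the 1e-2 convergence criterion.
#' @param blend_mode `"hermite"` or `"literal"`, see [blend_band()].
#' @param m_psi number of \eqn{\psi} samples per contour for lofting.
#' @param theta_samples \eqn{\theta} samples per band.
#' @param z_start,dz height of the first slice and slice spacing (mm).
#' @param spacing pixel spacing in mm/px; when given, all geometry is
#'   serialized in mm, else in pixels.
#' @param max_segment_points longest boundary run (in chain points) fitted
#'   by a single rational segment; longer runs get evenly spaced extra
#'   break points before fitting.
#' @param mesh_format `"stl"` or `"obj"`.
#' @param keep_going continue past per-slice stage errors (they are
#'   collected in the summary) instead of halting on the first.
#' @param verbose print per-stage progress.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, format = c("png", "contours"),
                            threshold = NULL, corner_k = 5L,
                            corner_cos = -0.6, nms_radius = corner_k,
                            ga = ga_config(target_error = 1e-6,
                                           generations = 60L),
                            blend_mode = "hermite",
                            m_psi = 100L, theta_samples = 9L,
                            z_start = 0, dz = 1, spacing = NULL,
                            max_segment_points = 90L,
                            mesh_format = c("stl", "obj"),
                            keep_going = FALSE, verbose = FALSE) {
  format <- match.arg(format)
  mesh_format <- match.arg(mesh_format)
  stopifnot(inherits(ga, "ga_config"))
  if (as.integer(m_psi) < 3L || as.integer(theta_samples) < 2L) {
    stop("grid sizes too small", call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir, format = format,
                 threshold = threshold, corner_k = as.integer(corner_k),
                 corner_cos = corner_cos,
                 nms_radius = as.integer(nms_radius), ga = ga,
                 blend_mode = blend_mode, m_psi = as.integer(m_psi),
                 theta_samples = as.integer(theta_samples),
                 z_start = z_start, dz = dz, spacing = spacing,
                 max_segment_points = as.integer(max_segment_points),
                 mesh_format = mesh_format,
                 keep_going = isTRUE(keep_going),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Break indices for boundary fitting
#'
#' [fit_boundary()] splits only at the indices it is given; a smooth run of
#' hundreds of points between two corners would then be fitted by a single
#' rational cubic, which cannot follow a long arc.  This helper augments
#' the corner set with evenly spaced filler breaks so that no segment
#' exceeds `max_pts` chain points.  On closed chains with no corners at
#' all, four equally spaced breaks are seeded first.
#'
#' @param n chain length in points.
#' @param corners detected corner indices (may be empty).
#' @param max_pts longest tolerated segment, in chain points.
#' @param closed logical: circular indexing.
#' @return strictly increasing integer break indices.
#' @export
segment_breaks <- function(n, corners, max_pts = 90L, closed = TRUE) {
  insert_breaks(as.integer(n), as.integer(corners), as.integer(max_pts),
                isTRUE(closed))
}

# break indices for fitting: corners plus evenly spaced fillers so no
# segment exceeds max_pts chain points
insert_breaks <- function(n, corners, max_pts, closed) {
  if (closed) {
    if (length(corners) == 0L) {
      corners <- unique(pmin(round(seq(1L, n + 1L, length.out = 5L))[1:4], n))
    }
    breaks <- sort(unique(corners))
    spans <- cbind(breaks, c(breaks[-1L], breaks[1L] + n))
  } else {
    breaks <- sort(unique(c(1L, corners, n)))
    spans <- cbind(breaks[-length(breaks)], breaks[-1L])
  }
  out <- integer(0)
  for (i in seq_len(nrow(spans))) {
    len <- spans[i, 2L] - spans[i, 1L]
    k <- max(0L, ceiling(len / max_pts) - 1L)
    fill <- if (k > 0L) round(seq(spans[i, 1L], spans[i, 2L],
                                  length.out = k + 2L)) else spans[i, ]
    out <- c(out, fill)
  }
  out <- sort(unique(((out - 1L) %% n) + 1L))
  out
}

# split a closed fracture loop (broken annulus traced as one chain) at its
# four gap corners into outer arc, inner arc and the two thickness caps
split_fracture_arcs <- function(chain, corners) {
  pts <- as_points(chain)
  n <- nrow(pts)
  if (length(corners) != 4L) {
    stop("cannot identify fracture gap: expected 4 corners, got ",
         length(corners), call. = FALSE)
  }
  segs <- lapply(1:4, function(k) {
    from <- corners[k]
    to <- if (k < 4L) corners[k + 1L] else corners[1L]
    idx <- if (from <= to) from:to else c(from:n, 1L:to)
    pts[idx, , drop = FALSE]
  })
  npts <- vapply(segs, nrow, integer(1))
  cap_idx <- order(npts)[1:2]
  arc_idx <- setdiff(1:4, cap_idx)
  centroid <- colMeans(pts)
  mean_r <- vapply(arc_idx, function(k) {
    mean(row_norms(sweep(segs[[k]], 2L, centroid)))
  }, numeric(1))
  outer <- segs[[arc_idx[which.max(mean_r)]]]
  inner <- segs[[arc_idx[which.min(mean_r)]]]
  list(outer = outer, inner = inner, caps = segs[cap_idx])
}

#' Reconstruct a missing-part curve between fracture gap endpoints
#'
#' Builds the rational cubic Ball segment bridging a fracture gap: it
#' interpolates the two gap endpoints and takes its end tangent directions
#' from the fitted boundary on either side, so the repaired contour
#' continues GC1-smoothly across the gap.  Tangent magnitudes use the
#' circle-aware Hermite scaling: with \eqn{\gamma} the turning angle
#' between the two end tangents, magnitudes are
#' \eqn{chord \cdot 4\tan(\gamma/4) / (2\sin(\gamma/2))}, which renders a
#' circular gap arc with the optimal cubic approximation and degrades
#' smoothly to plain chord length as \eqn{\gamma \to 0}.  With weights
#' \eqn{a = b = 2} the denominator is identically 1 and the segment is the
#' cubic Hermite interpolant in Ball form.
#'
#' @param p0,p1 gap endpoints (the curve runs p0 -> p1).
#' @param d0 tangent direction at `p0` (need not be normalized).
#' @param d1 tangent direction at `p1`.
#' @return a [rational_segment()] spanning the gap.
#' @export
reconstruct_gap <- function(p0, p1, d0, d1) {
  p0 <- as_point(p0); p1 <- as_point(p1)
  d0 <- as_point(d0); d1 <- as_point(d1)
  if (vnorm(d0) == 0 || vnorm(d1) == 0) {
    stop("gap tangent directions must be nonzero", call. = FALSE)
  }
  chord <- vnorm(p1 - p0)
  if (chord == 0) stop("gap endpoints coincide", call. = FALSE)
  d0 <- d0 / vnorm(d0)
  d1 <- d1 / vnorm(d1)
  gamma <- acos(min(1, max(-1, sum(d0 * d1))))
  scale <- if (gamma < 1e-6) chord else
    chord * 4 * tan(gamma / 4) / (2 * sin(gamma / 2))
  t0 <- scale * d0
  t1 <- scale * d1
  rational_segment(p0, 2 * p0 + t0, 2 * p1 - t1, p1, 2, 2)
}

#' Run the slice-to-surface reconstruction pipeline
#'
#' Executes the full reconstruction: read slices, binarize, extract
#' morphological boundaries, trace contours, detect corners, fit each
#' slice's outer boundary with a GC1 rational Ball chain (GA-optimized free
#' parameters), bridge fracture gaps where a broken ring is detected, stack
#' the fitted contours at equidistant heights, blend them into a surface
#' and write a triangle mesh.  All artifacts (per-slice chains/corners
#' JSON, fit JSON, contour-stack JSON, mesh, summary JSON) land in
#' `cfg$output_dir`; with a fixed GA seed reruns are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return the summary list, invisibly: per-slice max \eqn{E^2}, whether
#'   the \eqn{10^{-2}} stopping criterion was met, GA generations used,
#'   fracture information, stage timings and output files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[["elapsed"]]
  log <- list()
  note <- function(stage, t0) {
    log[[length(log) + 1L]] <<- list(stage = stage,
                                     seconds = proc.time()[["elapsed"]] - t0)
    if (cfg$verbose) message(sprintf("[%s] %.2fs", stage,
                                     proc.time()[["elapsed"]] - t0))
  }
  fail <- function(slice, stage, e) {
    msg <- sprintf("slice %d, stage %s: %s", slice, stage,
                   conditionMessage(e))
    if (cfg$keep_going) {
      warning(msg, call. = FALSE)
      NULL
    } else {
      stop(msg, call. = FALSE)
    }
  }
  scale <- if (is.null(cfg$spacing)) 1 else cfg$spacing
  units <- if (is.null(cfg$spacing)) "px" else "mm"

  # ---- stage: input -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (cfg$format == "png") {
    images <- read_image_stack(cfg$input)
    n_slices <- length(images)
  } else {
    chains_by_slice <- read_contours_csv(cfg$input)
    n_slices <- length(chains_by_slice)
  }
  if (n_slices < 2L) {
    stop("input error: need at least 2 slices in ", cfg$input, call. = FALSE)
  }
  note("input", t0)

  slice_summaries <- vector("list", n_slices)
  outer_curves <- vector("list", n_slices)
  gap_curves <- list()

  for (s in seq_len(n_slices)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      if (cfg$format == "png") {
        mask <- binarize(images[[s]], threshold = cfg$threshold,
                         spacing = cfg$spacing)
        boundary <- extract_boundary(mask)
        chains <- trace_contours(boundary)
      } else {
        chains <- chains_by_slice[[s]]
      }
      # scale to mm if spacing known
      chains <- lapply(chains, function(ch) {
        structure(as_points(ch) * scale, closed = attr(ch, "closed"))
      })
      corners <- lapply(chains, function(ch) {
        if (nrow(ch) > 2L * cfg$corner_k) {
          detect_corners(ch, k = cfg$corner_k,
                         cos_threshold = cfg$corner_cos,
                         nms_radius = cfg$nms_radius)
        } else {
          integer(0)
        }
      })
      write_chains_json(file.path(cfg$output_dir,
                                  sprintf("slice_%03d_chains.json", s)),
                        s, chains, corners, units = units)

      outer_chain <- chains[[1L]]
      outer_corners <- corners[[1L]]
      closed_chains <- sum(vapply(chains, function(ch)
        isTRUE(attr(ch, "closed")), logical(1)))
      fractured <- isTRUE(attr(outer_chain, "closed")) &&
        closed_chains == 1L && length(outer_corners) == 4L

      if (fractured) {
        arcs <- split_fracture_arcs(outer_chain, outer_corners)
        arc <- arcs$outer
        breaks <- insert_breaks(nrow(arc), integer(0),
                                cfg$max_segment_points, closed = FALSE)
        fit <- fit_boundary(arc, breaks, cfg$ga, closed = FALSE)
        der_end <- endpoint_derivatives(
          fit$chain$segments[[length(fit$chain$segments)]])$end
        der_start <- endpoint_derivatives(fit$chain$segments[[1L]])$start
        gap <- reconstruct_gap(arc[nrow(arc), ], arc[1L, ],
                               der_end, der_start)
        arc_pts <- sample_chain(fit$chain, 41L)
        gap_pts <- eval_rational(gap, seq(0, 1, length.out = 41L))
        full <- rbind(arc_pts, gap_pts[-1L, , drop = FALSE])
        full <- full[-nrow(full), , drop = FALSE]  # drop closure duplicate
        list(fit = fit, contour = full, gap = gap_pts,
             gap_endpoints = rbind(arc[nrow(arc), ], arc[1L, ]),
             fractured = TRUE)
      } else {
        breaks <- insert_breaks(nrow(outer_chain), outer_corners,
                                cfg$max_segment_points, closed = TRUE)
        fit <- fit_boundary(outer_chain, breaks, cfg$ga, closed = TRUE)
        contour <- sample_chain(fit$chain, 41L)
        contour <- contour[-nrow(contour), , drop = FALSE]
        list(fit = fit, contour = contour, gap = NULL,
             gap_endpoints = NULL, fractured = FALSE)
      }
    }, error = function(e) fail(s, "slice-processing", e))
    note(sprintf("slice %d", s), t0)
    if (is.null(res)) next

    fit <- res$fit
    outer_curves[[s]] <- res$contour
    if (res$fractured) {
      gap_curves[[as.character(s)]] <- res$gap
    }
    jsonlite::write_json(
      list(units = units, slice = s,
           knots = unname(fit$chain$knots),
           weights = unname(fit$weights), lambdas = fit$lambdas,
           inner_controls = lapply(fit$chain$segments, function(sg)
             unname(sg$c_pt)),
           b_first = unname(fit$chain$segments[[1L]]$b_pt),
           errors = fit$errors, converged = fit$converged,
           generations = fit$generations,
           fractured = res$fractured,
           gap_endpoints = if (!is.null(res$gap_endpoints))
             unname(res$gap_endpoints)),
      file.path(cfg$output_dir, sprintf("slice_%03d_fit.json", s)),
      auto_unbox = TRUE, digits = NA)
    slice_summaries[[s]] <- list(
      slice = s, max_e2 = max(fit$errors),
      # the classic stopping criterion on the optimization error
      meets_tolerance = max(fit$errors) <= 1e-2,
      generations = unname(fit$generations),
      fractured = res$fractured)
  }

  fitted <- !vapply(outer_curves, is.null, logical(1))
  if (sum(fitted) < 2L) {
    stop("fewer than 2 slices fitted; cannot build a surface", call. = FALSE)
  }

  # ---- stage: lofting -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  aligned <- resample_aligned(outer_curves[fitted], cfg$m_psi, closed = TRUE)
  stack <- stack_to_3d(aligned,
                       z_start = cfg$z_start +
                         (which(fitted)[1L] - 1L) * cfg$dz,
                       dz = cfg$dz, closed = TRUE)
  jsonlite::write_json(
    list(units = units, z = stack$z,
         contours = lapply(seq_len(dim(stack$points)[1L]), function(i)
           unname(stack$points[i, , ]))),
    file.path(cfg$output_dir, "contour_stack.json"),
    auto_unbox = TRUE, digits = NA)
  surface <- build_surface(stack, cfg$theta_samples, mode = cfg$blend_mode)
  mesh <- surface_to_mesh(surface)
  mesh_file <- file.path(cfg$output_dir, paste0("surface.", cfg$mesh_format))
  if (cfg$mesh_format == "stl") write_stl(mesh, mesh_file) else
    write_obj(mesh, mesh_file)
  note("lofting", t0)

  # ---- stage: fracture patch ---------------------------------------------
  patch_file <- NULL
  if (length(gap_curves) >= 2L) {
    t0 <- proc.time()[["elapsed"]]
    gs <- as.integer(names(gap_curves))
    aligned_g <- resample_aligned(unname(gap_curves), max(cfg$m_psi %/% 2L, 9L),
                                  closed = FALSE)
    stack_g <- stack_to_3d(aligned_g,
                           z_start = cfg$z_start + (min(gs) - 1L) * cfg$dz,
                           dz = cfg$dz, closed = FALSE)
    surf_g <- build_surface(stack_g, cfg$theta_samples,
                            mode = cfg$blend_mode)
    mesh_g <- surface_to_mesh(surf_g, closed = FALSE)
    patch_file <- file.path(cfg$output_dir,
                            paste0("fracture.", cfg$mesh_format))
    if (cfg$mesh_format == "stl") write_stl(mesh_g, patch_file) else
      write_obj(mesh_g, patch_file)
    note("fracture-patch", t0)
  }

  summary <- list(
    n_slices = n_slices,
    seed = cfg$ga$seed,
    units = units,
    slices = slice_summaries[fitted],
    all_meet_tolerance = all(vapply(slice_summaries[fitted], function(x)
      isTRUE(x$meets_tolerance), logical(1))),
    fractured_slices = as.integer(names(gap_curves)),
    mesh = basename(mesh_file),
    fracture_mesh = if (!is.null(patch_file)) basename(patch_file))
  # summary.json is deterministic under a fixed seed; timings go separately
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(stages = log, total_seconds = proc.time()[["elapsed"]] - t_all),
    file.path(cfg$output_dir, "timings.json"), auto_unbox = TRUE, digits = 6)
  summary$log <- log
  invisible(summary)
}
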