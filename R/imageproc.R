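#' Binarize a grayscale slice
#'
#' Thresholds a 2D intensity grid into a \{0, 1\} foreground mask.  CT bone
#' is bright, so by default foreground is the above-threshold set; use
#' `polarity = "dark"` for inverted material (e.g. printed figures).  With
#' no explicit threshold, Otsu's criterion is applied to the intensity
#' histogram.
#'
#' @param gray numeric matrix of intensities (rows = image rows).
#' @param threshold optional explicit threshold; a pixel is foreground iff
#'   its (polarity-adjusted) intensity is >= `threshold`.
#' @param polarity `"bright"` (default) or `"dark"`.
#' @param spacing optional pixel spacing in mm, carried as an attribute.
#' @return an integer \{0, 1\} matrix of class `binary_image`.
#' @export
binarize <- function(gray, threshold = NULL, polarity = c("bright", "dark"),
                     spacing = NULL) {
  polarity <- match.arg(polarity)
  if (!is.matrix(gray) || !is.numeric(gray) || length(gray) == 0L) {
    stop("`gray` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (polarity == "dark") gray <- max(gray) - gray
  if (is.null(threshold)) {
    rng <- range(gray)
    if (rng[1L] == rng[2L]) {
      stop("cannot threshold a constant image; give `threshold` explicitly",
           call. = FALSE)
    }
    g01 <- (gray - rng[1L]) / (rng[2L] - rng[1L])
    t01 <- EBImage::otsu(EBImage::Image(t(g01)))
    threshold <- rng[1L] + t01 * (rng[2L] - rng[1L])
  }
  mask <- matrix(as.integer(gray >= threshold), nrow(gray), ncol(gray))
  structure(mask, class = c("binary_image", class(mask)),
            spacing = spacing, threshold = threshold)
}

#' Morphological boundary extraction
#'
#' Computes the one-pixel-thick object boundary
#' \eqn{\beta(A) = A - (A \ominus B)}: the foreground set minus its erosion
#' by a 3 x 3 structuring element.  The full 8-connected 3 x 3 block is the
#' default; `elem = "cross"` switches to the 4-connected cross.  Pixels
#' outside the image count as background, so objects touching the border
#' contribute their border pixels to the boundary.
#'
#' @param mask a \{0, 1\} matrix (e.g. from [binarize()]) with at least one
#'   foreground pixel.
#' @param elem `"box"` (default) or `"cross"` structuring element.
#' @return a \{0, 1\} matrix of the same shape marking boundary pixels.
#' @export
extract_boundary <- function(mask, elem = c("box", "cross")) {
  elem <- match.arg(elem)
  if (!is.matrix(mask) || length(mask) == 0L) {
    stop("`mask` must be a non-empty matrix", call. = FALSE)
  }
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0L) stop("empty foreground: nothing to extract", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  offs <- if (elem == "box") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(0L, -1L, 1L, 0L, 0L), dc = c(0L, 0L, 0L, -1L, 1L))
  }
  er <- matrix(1L, nr, nc)
  for (i in seq_len(nrow(offs))) {
    er <- er & pad[(2:(nr + 1L)) + offs$dr[i], (2:(nc + 1L)) + offs$dc[i]]
  }
  out <- m & !er
  matrix(as.integer(out), nr, nc)
}

# 8-neighbour offsets, 4-connected first (preferred when walking chains)
.nbr_offsets <- rbind(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L),
                      c(1L, 1L), c(1L, -1L), c(-1L, -1L), c(-1L, 1L))

#' Trace ordered contour chains from a boundary pixel set
#'
#' Partitions the boundary pixels into 8-connected components and walks each
#' component as an ordered chain: closed chains for rings (returned
#' counterclockwise in standard (x, y) orientation), open chains for arcs
#' with free endpoints.  The walk prefers 4-neighbours over diagonals so
#' that staircase pixels are not skipped; a component that cannot be walked
#' as a simple chain (e.g. width-2 blobs or junctions) raises a tracing
#' error naming the component.
#'
#' Closed chains come first, ordered by decreasing enclosed area (outer
#' contour first); open chains follow, longest first.
#'
#' @param boundary \{0, 1\} matrix from [extract_boundary()].
#' @return list of chains; each is an n x 2 matrix of 0-based (x, y)
#'   coordinates (x = col - 1, y = nrow - row) with attributes `closed`
#'   (logical) and `rowcol` (the 1-based pixel indices in trace order).
#' @export
trace_contours <- function(boundary) {
  if (!is.matrix(boundary) || sum(boundary != 0) == 0L) {
    stop("`boundary` must be a matrix with at least one boundary pixel",
         call. = FALSE)
  }
  nr <- nrow(boundary); nc <- ncol(boundary)
  inset <- boundary != 0
  labels <- matrix(0L, nr, nc)
  px <- which(inset, arr.ind = TRUE)

  # label 8-connected components by BFS
  ncomp <- 0L
  for (s in seq_len(nrow(px))) {
    if (labels[px[s, 1L], px[s, 2L]] != 0L) next
    ncomp <- ncomp + 1L
    queue <- matrix(px[s, ], ncol = 2L)
    labels[px[s, 1L], px[s, 2L]] <- ncomp
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      for (k in 1:8) {
        r <- cur[1L] + .nbr_offsets[k, 1L]
        c <- cur[2L] + .nbr_offsets[k, 2L]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            inset[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- ncomp
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }

  chains <- vector("list", ncomp)
  for (comp in seq_len(ncomp)) {
    cpx <- which(labels == comp, arr.ind = TRUE)
    npix <- nrow(cpx)
    if (npix == 1L) {
      chains[[comp]] <- structure(cpx, closed = FALSE)
      next
    }
    compset <- matrix(FALSE, nr, nc)
    compset[cpx] <- TRUE
    deg <- vapply(seq_len(npix), function(i) {
      r <- cpx[i, 1L]; c <- cpx[i, 2L]
      sum(vapply(1:8, function(k) {
        rr <- r + .nbr_offsets[k, 1L]; cc <- c + .nbr_offsets[k, 2L]
        rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && compset[rr, cc]
      }, logical(1)))
    }, integer(1))

    endpoints <- which(deg == 1L)
    closed <- length(endpoints) == 0L

    # Moore border following around the component, starting at the
    # topmost-leftmost pixel with its (background) west neighbour as
    # backtrack; stops on Jacob's criterion.  On one-pixel-wide chains this
    # visits every pixel exactly once in border order; where rasterization
    # makes the boundary two pixels thick the tour passes some pixels twice
    # and skips enclosed ones, and duplicates are dropped keeping the first
    # occurrence.
    start <- if (closed) {
      # topmost-leftmost pixel: its west neighbour is guaranteed background
      ord <- order(cpx[, 1L], cpx[, 2L])
      cpx[ord[1L], ]
    } else {
      # open arcs must be walked from a free endpoint, or the deduped tour
      # would splice the two directions of travel
      cpx[endpoints[1L], ]
    }
    # clockwise direction ring starting west
    cw <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
    inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
      compset[r, c]
    bdir <- 1L
    while (inside(start[1L] + cw[bdir, 1L], start[2L] + cw[bdir, 2L])) {
      bdir <- bdir + 1L  # some direction is background (deg < 8)
    }
    tour <- matrix(NA_integer_, 4L * npix + 8L, 2L)
    tour[1L, ] <- start
    tlen <- 1L
    cur <- start
    seen <- new.env(hash = TRUE, parent = emptyenv())
    state_key <- function(p, b) sprintf("%d,%d,%d", p[1L], p[2L], b)
    assign(state_key(cur, bdir), TRUE, envir = seen)
    repeat {
      found <- FALSE
      for (s in 1:8) {
        k <- ((bdir - 1L + s - 1L) %% 8L) + 1L
        rr <- cur[1L] + cw[k, 1L]
        cc <- cur[2L] + cw[k, 2L]
        if (inside(rr, cc)) {
          # new backtrack: direction of the previously scanned neighbour
          prev_k <- ((k - 2L) %% 8L) + 1L
          nxt <- c(rr, cc)
          bdir_nbr <- cur + cw[prev_k, ]
          bdir <- which(cw[, 1L] == bdir_nbr[1L] - rr &
                          cw[, 2L] == bdir_nbr[2L] - cc)
          cur <- nxt
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("tracing error: component ", comp,
             " cannot be border-followed", call. = FALSE)
      }
      key <- state_key(cur, bdir)
      if (exists(key, envir = seen, inherits = FALSE)) break
      assign(key, TRUE, envir = seen)
      tlen <- tlen + 1L
      if (tlen > nrow(tour)) {
        stop("tracing error: component ", comp,
             " is not a traceable chain (tour did not close)", call. = FALSE)
      }
      tour[tlen, ] <- cur
    }
    tour <- tour[seq_len(tlen), , drop = FALSE]
    dup <- duplicated(tour[, 1L] * (nc + 1L) + tour[, 2L])
    chains[[comp]] <- structure(tour[!dup, , drop = FALSE], closed = closed)
  }

  # convert to standard-orientation (x, y), enforce CCW on closed chains
  out <- lapply(chains, function(p) {
    closed <- attr(p, "closed")
    xy <- cbind(x = p[, 2L] - 1L, y = nr - p[, 1L])
    if (closed && nrow(xy) >= 3L && signed_area(xy) < 0) {
      xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    structure(xy, closed = closed, rowcol = unname(p))
  })
  closed_flags <- vapply(out, attr, logical(1), "closed")
  areas <- vapply(out, function(ch) {
    if (attr(ch, "closed")) abs(signed_area(ch)) else -nrow(ch)
  }, numeric(1))
  ord <- c(which(closed_flags)[order(-areas[closed_flags])],
           which(!closed_flags)[order(areas[!closed_flags])])
  out[ord]
}

#' Detect corner points on a boundary chain
#'
#' k-cosine corner detector: at chain point \eqn{p_i}, the angle measure is
#' the cosine of the angle between the backward arm \eqn{p_{i-k} - p_i}
#' and the forward arm \eqn{p_{i+k} - p_i}.  Straight runs give -1, a right
#' angle gives 0.  Indices whose cosine exceeds `cos_threshold` and is a
#' local maximum within `nms_radius` along the chain are reported.  For
#' open chains the two endpoints are always included: the ends of open data
#' are segment breaks by definition (they anchor fracture-gap fitting).
#'
#' @param chain n x 2 matrix of ordered points, typically from
#'   [trace_contours()]; the `closed` attribute (default `TRUE`) selects
#'   circular or open indexing.
#' @param k neighbourhood half-width (arm length in chain samples).
#' @param cos_threshold detection threshold on the k-cosine (default -0.6:
#'   flags turns sharper than about 127 degrees while ignoring smooth arcs,
#'   whose k-cosine stays near -1).
#' @param nms_radius non-maximum suppression radius along the chain
#'   (default `k`).
#' @return strictly increasing integer vector of corner indices.
#' @export
detect_corners <- function(chain, k = 5L, cos_threshold = -0.6,
                           nms_radius = k) {
  pts <- as_points(chain)
  n <- nrow(pts)
  k <- as.integer(k)
  closed <- isTRUE(attr(chain, "closed")) || is.null(attr(chain, "closed"))
  if (n <= 2L * k) {
    stop("chain too short for k = ", k, " (need more than 2k points)",
         call. = FALSE)
  }
  idx <- if (closed) seq_len(n) else (k + 1L):(n - k)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  back <- pts[wrap(idx - k), , drop = FALSE] - pts[idx, , drop = FALSE]
  fwd <- pts[wrap(idx + k), , drop = FALSE] - pts[idx, , drop = FALSE]
  cosv <- rowSums(back * fwd) / (row_norms(back) * row_norms(fwd))

  cand <- idx[cosv > cos_threshold]
  cand_cos <- cosv[cosv > cos_threshold]
  if (length(cand)) {
    # greedy non-maximum suppression, stable in (cosine desc, index asc)
    ord <- order(-cand_cos, cand)
    keep <- integer(0)
    circ_dist <- function(a, b) {
      d <- abs(a - b)
      if (closed) pmin(d, n - d) else d
    }
    for (i in ord) {
      if (!length(keep) || all(circ_dist(cand[i], cand[keep]) > nms_radius)) {
        keep <- c(keep, i)
      }
    }
    corners <- sort(cand[keep])
  } else {
    corners <- integer(0)
  }
  if (!closed) corners <- sort(unique(c(1L, corners, n)))
  corners
}
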