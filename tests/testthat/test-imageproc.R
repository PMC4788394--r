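test_that("binarize applies explicit and Otsu thresholds", {
  img <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(unclass(binarize(img, threshold = 128))[, ],
               matrix(c(0L, 1L, 1L, 0L), 2, 2)[, ])
  # all-background result is allowed with an explicit threshold
  expect_equal(sum(binarize(matrix(0, 4, 4), threshold = 1)), 0)
  expect_error(binarize(matrix(5, 4, 4)), "constant")
  # Otsu separates a clearly bimodal image like the explicit threshold
  set.seed(2)
  bi <- matrix(sample(c(10, 240), 400, replace = TRUE), 20, 20)
  expect_equal(unclass(binarize(bi))[, ],
               unclass(binarize(bi, threshold = 128))[, ])
})

test_that("boundary of a filled 5x5 square has exactly its 16 border pixels", {
  m <- matrix(0L, 9, 9)
  m[3:7, 3:7] <- 1L
  b <- extract_boundary(m)
  expect_equal(sum(b), 16)
  expect_equal(b, brute_force_boundary(m))
  # single pixel erodes away entirely: it is its own boundary
  s <- matrix(0L, 5, 5); s[3, 3] <- 1L
  expect_equal(extract_boundary(s), s)
  expect_error(extract_boundary(matrix(0L, 3, 3)), "empty")
})

test_that("boundary extraction equals the brute-force definition on random images", {
  set.seed(19)
  for (rep in 1:100) {
    m <- matrix(rbinom(15 * 15, 1, 0.5), 15, 15)
    if (sum(m) == 0) m[8, 8] <- 1L
    expect_identical(extract_boundary(m), brute_force_boundary(m))
    expect_identical(extract_boundary(m, elem = "cross"),
                     brute_force_boundary(m, elem = "cross"))
  }
})

test_that("the boundary is always a subset of the foreground", {
  set.seed(29)
  for (rep in 1:20) {
    m <- matrix(rbinom(20 * 20, 1, 0.4), 20, 20)
    if (sum(m) == 0) m[1, 1] <- 1L
    b <- extract_boundary(m)
    expect_true(all(m[b == 1] == 1))
  }
})

test_that("a disc boundary matches the brute-force oracle", {
  xy <- expand.grid(r = 1:100, c = 1:100)
  m <- matrix(as.integer((xy$r - 50)^2 + (xy$c - 50)^2 <= 30^2), 100, 100)
  expect_identical(extract_boundary(m), brute_force_boundary(m))
})

test_that("tracing a square ring yields one closed counterclockwise chain", {
  m <- matrix(0L, 9, 9)
  m[3:7, 3:7] <- 1L
  b <- extract_boundary(m)
  ch <- trace_contours(b)
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]), 16L)
  expect_true(attr(ch[[1]], "closed"))
  # counterclockwise in standard orientation: positive signed area
  xy <- ch[[1]]
  x <- xy[, 1]; y <- xy[, 2]
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(area, 0)
  # the chain is a partition of the boundary set here (1-px-wide ring)
  expect_equal(sort(xy[, 1] * 100 + xy[, 2]),
               sort((which(b == 1, arr.ind = TRUE)[, 2] - 1) * 100 +
                      9 - which(b == 1, arr.ind = TRUE)[, 1]))
  # consecutive pixels 8-adjacent, closure included
  d <- pmax(abs(diff(c(x, x[1]))), abs(diff(c(y, y[1]))))
  expect_true(all(d == 1))
})

test_that("an annulus traces to outer-then-inner chains, disjoint shapes to two", {
  spec <- phantom_spec(n_slices = 2, size = 96, r_out = 15, thickness = 4,
                       spacing = 0.5)
  b <- extract_boundary(binarize(rasterize_slices(spec)[[1]],
                                 threshold = 128))
  ch <- trace_contours(b)
  expect_length(ch, 2L)
  expect_true(all(vapply(ch, attr, logical(1), "closed")))
  # outer first: larger mean radius from the shared centre
  ctr <- spec$center / spec$spacing
  mr <- vapply(ch, function(p) {
    mean(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
  }, numeric(1))
  expect_gt(mr[1], mr[2])

  m <- matrix(0L, 24, 24)
  m[2:6, 2:6] <- 1L
  m[12:19, 12:19] <- 1L
  expect_length(trace_contours(extract_boundary(m)), 2L)
})

test_that("open one-pixel arcs trace endpoint to endpoint", {
  m <- matrix(0L, 20, 20)
  for (i in 3:15) m[i, i + 2L] <- 1L
  ch <- trace_contours(m)
  expect_length(ch, 1L)
  expect_false(attr(ch[[1]], "closed"))
  expect_equal(nrow(ch[[1]]), 13L)
  # walked monotonically from one free end to the other
  expect_equal(abs(as.numeric(ch[[1]][1, 1] - ch[[1]][13, 1])), 12)
})

test_that("corner detection finds polygon vertices and ignores smooth arcs", {
  # right angles: 4 corners at the square's vertices
  sq <- ngon_chain(4, r = 40)
  co <- detect_corners(sq, k = 5, cos_threshold = -0.5)
  expect_length(co, 4L)
  # detected indices sit at the vertices (within one chain step)
  vert_idx <- which(apply(sq, 1, function(p) {
    any(abs(abs(p) - c(40 * sqrt(2) / 2, 40 * sqrt(2) / 2)) < 1e-6) ||
      max(abs(abs(p) - c(40, 0))) < 1e-6 || max(abs(abs(p) - c(0, 40))) < 1e-6
  }))
  for (ci in co) expect_lte(min(abs(ci - vert_idx)), 1)
  # circle of radius 50: no corners
  expect_length(detect_corners(ngon_chain(180, r = 50), k = 5), 0L)
})

test_that("corner count equals n on regular n-gons with default parameters", {
  for (n in 3:6) {
    expect_length(detect_corners(ngon_chain(n)), n)
  }
})

test_that("open chains always report their endpoints as breaks", {
  t <- seq(0, pi, length.out = 80)
  arc <- structure(cbind(50 * cos(t), 50 * sin(t)), closed = FALSE)
  co <- detect_corners(arc, k = 5)
  expect_true(1L %in% co)
  expect_true(80L %in% co)
})

test_that("chains shorter than the detector window are rejected", {
  short <- structure(cbind(1:8, 1), closed = FALSE)
  expect_error(detect_corners(short, k = 5), "too short")
})
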