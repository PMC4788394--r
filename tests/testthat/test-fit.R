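test_that("chord-length parameters match direct evaluation", {
  expect_equal(chord_length_params(rbind(c(0, 0), c(1, 1))), c(0, 1))
  expect_equal(chord_length_params(cbind(0:4, 0)), c(0, 0.25, 0.5, 0.75, 1))
  # chords 3 and 4, total 7
  expect_equal(chord_length_params(rbind(c(0, 0), c(3, 0), c(3, 4))),
               c(0, 3 / 7, 1))
  expect_error(chord_length_params(rbind(c(1, 1), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("chord-length parameters are monotone with pinned endpoints", {
  set.seed(3)
  for (rep in 1:500) {
    m <- sample(2:30, 1)
    pts <- cbind(cumsum(runif(m, 0.1, 1)), rnorm(m))
    th <- chord_length_params(pts)
    expect_identical(th[1], 0)
    expect_identical(th[m], 1)
    expect_true(all(diff(th) > 0))
  }
})

test_that("NMSE matches hand-computed values and detects interpolation", {
  # constant curve at origin vs datum (3,4): 25/25
  expect_equal(nmse(matrix(0, 1, 2), rbind(c(3, 4)), params = 0), 1)
  # datum (3,4) approximated by (3,3): 1/25
  expect_equal(nmse(rbind(c(3, 3)), rbind(c(3, 4)), params = 0), 0.04)
  # exact interpolation gives zero
  seg <- rational_segment(c(1, 1), c(4, 6), c(6, 4), c(5, 1), 1.2, 0.8)
  th <- seq(0, 1, length.out = 9)
  expect_equal(nmse(seg, eval_rational(seg, th), th), 0)
  expect_error(nmse(matrix(0, 2, 2), matrix(0, 2, 2)), "origin")
})

test_that("NMSE is origin-dependent: a common translation changes the error", {
  pts <- rbind(c(1, 0), c(2, 1), c(3, 0))
  fitted <- pts + 0.1
  e1 <- nmse(fitted, pts, params = c(0, 0.5, 1))
  e2 <- nmse(fitted + 100, pts + 100, params = c(0, 0.5, 1))
  expect_gt(e1, 0)
  expect_false(isTRUE(all.equal(e1, e2)))
})

test_that("least squares recovers inner coefficients from representable data", {
  set.seed(9)
  for (rep in 1:20) {
    seg <- rational_segment(runif(2, -2, 2), runif(2, -4, 4),
                            runif(2, -4, 4), runif(2, -2, 2),
                            runif(1, 0.3, 4), runif(1, 0.3, 4))
    th <- sort(c(0, runif(10), 1))
    dat <- eval_rational(seg, th)
    ls <- least_squares_controls(dat, th, seg$a_w, seg$b_w)
    expect_equal(ls$b_pt, seg$b_pt, tolerance = 1e-8)
    expect_equal(ls$c_pt, seg$c_pt, tolerance = 1e-8)
    # with B pinned, C alone is still recovered
    ls2 <- least_squares_controls(dat, th, seg$a_w, seg$b_w,
                                  b_fixed = seg$b_pt)
    expect_equal(ls2$c_pt, seg$c_pt, tolerance = 1e-8)
  }
})

test_that("endpoints alone leave the system under-determined", {
  pts <- rbind(c(0, 0), c(1, 1))
  expect_error(least_squares_controls(pts, c(0, 1), 1, 1),
               "under-determined")
})

test_that("symmetric data with equal weights give mirror-image coefficients", {
  x <- seq(-1, 1, length.out = 11)
  pts <- cbind(x, x^2)
  th <- chord_length_params(pts)
  ls <- least_squares_controls(pts, th, 1.3, 1.3)
  expect_equal(ls$b_pt[1], -ls$c_pt[1], tolerance = 1e-8)
  expect_equal(ls$b_pt[2], ls$c_pt[2], tolerance = 1e-8)
})

test_that("GA fitting is deterministic and leaves caller RNG state intact", {
  pts <- circle_points(40, r = 30, cx = 50, cy = 50)
  segs <- list(rbind(pts[1:21, ]), rbind(pts[21:40, ], pts[1, ]))
  cfg <- ga_config(seed = 99, generations = 10)
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  f1 <- ga_optimize(segs, cfg)
  f2 <- ga_optimize(segs, cfg)
  after <- runif(1)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$errors, f2$errors)
  expect_identical(f1$lambdas, f2$lambdas)
  expect_identical(before, after)  # GA did not disturb the caller's stream
})

test_that("straight-line data are fitted essentially exactly at any weights", {
  pts <- cbind(seq(1, 5, length.out = 12), seq(2, 4, length.out = 12))
  fit <- ga_optimize(list(pts), ga_config(seed = 2, generations = 3))
  expect_lt(fit$errors[1], 1e-10)
})

test_that("best GA fitness never increases across generations", {
  set.seed(77)
  t <- seq(0, pi / 2, length.out = 25)
  pts <- cbind(40 * cos(t), 40 * sin(t))
  fit <- ga_optimize(list(pts),
                     ga_config(seed = 5, generations = 40,
                               target_error = 1e-14))
  hist <- fit$best_history[[1]]
  expect_gt(length(hist), 1L)
  expect_true(all(diff(hist) <= 0))
})

test_that("refitting data sampled from known chains recovers the curve shape", {
  # 40 samples per segment of a known chain, refit, shape compared by
  # symmetric Hausdorff distance relative to the bounding-box diagonal.
  # Sequential GC1-coupled optimization is greedy, so an occasional chain
  # settles at a few-percent shape error; the bulk recover below 1%.
  rel_err <- vapply(1:10, function(sd) {
    set.seed(sd)
    ch <- tame_chain()
    th <- seq(0, 1, length.out = 40)
    segs <- lapply(ch$segments, function(s) eval_rational(s, th))
    fit <- ga_optimize(segs, ga_config(seed = 8, generations = 60,
                                       target_error = 1e-9))
    orig <- sample_chain(ch, 201)
    fitted <- sample_chain(fit$chain, 201)
    pts_all <- do.call(rbind, segs)
    bbox <- apply(pts_all, 2, range)
    diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
    max(hausdorff_to(fitted, orig), hausdorff_to(orig, fitted)) / diag_len
  }, numeric(1))
  expect_gte(sum(rel_err < 1e-2), 8)
  expect_lt(max(rel_err), 3e-2)
})

test_that("boundary fitting splits at corners and meets the stopping criterion", {
  # square with its 4 corners: straight segments are representable
  sq <- ngon_chain(4, r = 40)
  corners <- detect_corners(sq, k = 5)
  expect_length(corners, 4L)
  fit <- fit_boundary(sq, corners, ga_config(seed = 3, generations = 5))
  expect_length(fit$segments, 4L)
  expect_true(all(fit$errors <= 1e-2))
  # circle with 4 synthetic corners
  circ <- circle_points(120, r = 45, cx = 60, cy = 60)
  fitc <- fit_boundary(circ, c(1, 31, 61, 91), ga_config(seed = 3))
  expect_true(fitc$converged)
  expect_true(all(fitc$errors <= 1e-2))
})

test_that("degenerate segmentations raise the documented errors", {
  circ <- circle_points(20, r = 10)
  expect_error(fit_boundary(circ, integer(0)), "cannot segment")
  expect_error(fit_boundary(circ, seq_len(20)), "under-determined")
  expect_error(ga_optimize(list(), ga_config()), "non-empty")
})

test_that("GA configuration validates its fields", {
  expect_error(ga_config(pop_size = 1), ">= 2")
  expect_error(ga_config(p_crossover = 1.2), "0, 1")
  expect_error(ga_config(target_error = 0), "positive")
  expect_error(ga_config(lower = 0), "positive")
})
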