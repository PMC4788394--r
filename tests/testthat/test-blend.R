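test_that("stacking assigns equidistant heights and validates input", {
  circ <- circle_points(12)
  st <- stack_to_3d(list(circ, circ, circ), z_start = 0, dz = 2)
  expect_equal(st$z, c(0, 2, 4))
  expect_true(all(diff(st$z) > 0))
  expect_error(stack_to_3d(list(circ), 0, 1), "at least 2")
  expect_error(stack_to_3d(list(circ, circ), 0, -1), "positive")
  expect_error(stack_to_3d(list(circ, circle_points(13)), 0, 1),
               "same number")
})

test_that("identical closed contours resample to identical aligned samples", {
  circ <- circle_points(100, r = 20)
  al <- resample_aligned(list(circ, circ), 48)
  expect_equal(al[1, , ], al[2, , ])
})

test_that("cyclic start alignment undoes a rotation of the sampling origin", {
  c1 <- circle_points(100, r = 30)
  c2 <- circle_points(100, r = 30, phase = 0.41)
  al <- resample_aligned(list(c1, c2), 64)
  d <- max(sqrt(rowSums((al[1, , ] - al[2, , ])^2)))
  expect_lt(d, 2 * pi * 30 / 64)
})

test_that("open arcs keep their endpoints under resampling", {
  t <- seq(0, pi / 2, length.out = 37)
  a1 <- cbind(10 * cos(t), 10 * sin(t))
  a2 <- cbind(12 * cos(t), 12 * sin(t))
  a2[1, ] <- a1[1, ]; a2[37, ] <- a1[37, ]  # shared gap endpoints
  al <- resample_aligned(list(a1, a2), 21, closed = FALSE)
  expect_equal(al[1, 1, ], unname(a1[1, ]))
  expect_equal(al[2, 1, ], unname(a1[1, ]))
  expect_equal(al[1, 21, ], unname(a1[37, ]))
  expect_equal(al[2, 21, ], unname(a1[37, ]))
  expect_error(resample_aligned(list(rbind(c(1, 1), c(1, 1))), 5,
                                closed = FALSE), "zero length")
})

test_that("tangent field degenerate rules fire exactly", {
  # cylinder: all differences vanish
  circ <- circle_points(16, r = 5)
  v <- tangent_field(stack_to_3d(list(circ, circ, circ), 0, 1))
  expect_equal(max(abs(v)), 0)
  # coincident triple at one sample only
  c1 <- circle_points(16, r = 5)
  c2 <- circle_points(16, r = 6)
  c2[3, ] <- c1[3, ]
  st <- stack_to_3d(list(c1, c2, c1), 0, 1)
  v2 <- tangent_field(st)
  expect_equal(v2[2, 3, ], c(0, 0))
  # antiparallel multiples of one unit vector: exact cancellation
  stap <- stack_to_3d(list(rbind(c(0.5, 0)), rbind(c(0, 0)),
                           rbind(c(1, 0))), 0, 1)
  expect_equal(sqrt(sum(tangent_field(stap)[2, , ]^2)), 0)
})

test_that("cone contours give the closed-form radial tangent", {
  psi <- (0:47) / 48
  u <- cbind(cos(2 * pi * psi), sin(2 * pi * psi))
  r0 <- 18; dr <- 4; dz <- 2
  cones <- lapply(1:4, function(i) (r0 + (i - 1) * dr) * u)
  v <- tangent_field(stack_to_3d(cones, 0, dz))
  for (i in 2:3) expect_equal(v[i, , ], (dr / dz) * u, tolerance = 1e-12)
  # one-sided boundary rule
  expect_equal(v[1, , ], (dr / dz) * u, tolerance = 1e-12)
})

test_that("vertically collinear samples match the comonotone closed form", {
  set.seed(53)
  for (rep in 1:25) {
    lam <- runif(1, 0.1, 3); mu <- runif(1, 0.1, 3)
    ang <- runif(1, 0, 2 * pi)
    vs <- c(cos(ang), sin(ang))
    z <- cumsum(c(0, runif(2, 0.5, 2)))
    cm <- runif(2, -5, 5)
    ci <- cm + mu * vs
    cp <- ci + lam * vs
    st <- stack_to_3d(list(rbind(cm), rbind(ci), rbind(cp)), 0, 1)
    st$z <- z
    v <- tangent_field(st)[2, 1, ]
    cf <- cranioball:::tangent_collinear_closed_form(
      lam, mu, z[2] - z[1], z[3] - z[2], vs)
    expect_equal(v, cf, tolerance = 1e-12)
  }
})

test_that("hermite blending interpolates contours and reproduces a cylinder", {
  circ <- circle_points(32, r = 7)
  v0 <- matrix(0, 32, 2)
  b <- blend_band(circ, circ, v0, v0, 0, 1, theta = seq(0, 1, 0.125))
  for (t in 1:9) expect_equal(b[t, , ], unname(circ))
  # endpoint rows equal the inputs exactly for distinct contours too
  c2 <- circle_points(32, r = 9)
  b2 <- blend_band(circ, c2, v0, v0, 0, 1)
  expect_identical(b2[1, , ], unname(circ))
  expect_identical(b2[9, , ], unname(c2))
})

test_that("the literal reading of the interpolant does not reproduce a cylinder", {
  circ <- circle_points(16, r = 7)
  v0 <- matrix(0, 16, 2)
  th <- seq(0, 1, length.out = 9)
  bl <- blend_band(circ, circ, v0, v0, 0, 1, theta = th, mode = "literal")
  # interior values shrink by the factor (1-theta)^2 + theta^2 < 1
  expect_equal(bl[5, , ], unname(circ) * 0.5, tolerance = 1e-12)
})

test_that("the blended surface reproduces cylinder and cone exactly", {
  psi <- (0:95) / 96
  u <- cbind(cos(2 * pi * psi), sin(2 * pi * psi))
  # cylinder
  circ <- 25 * u
  su <- build_surface(stack_to_3d(list(circ, circ, circ), 0, 1), 9)
  for (band in su$bands) {
    r <- sqrt(band[, , 1]^2 + band[, , 2]^2)
    expect_lt(max(abs(r - 25)), 1e-9)
  }
  # cone: linear radial profile is reproduced by the cubic
  cones <- lapply(1:4, function(i) (20 + (i - 1) * 3) * u)
  suc <- build_surface(stack_to_3d(cones, 0, 2), 17)
  for (band in suc$bands) {
    r <- sqrt(band[, , 1]^2 + band[, , 2]^2)
    rtrue <- 20 + 3 * band[, , 3] / 2
    expect_lt(max(abs(r - rtrue)), 1e-3 * 20)
  }
})

test_that("surface heights are the exact linear blend and rows are shared", {
  set.seed(71)
  cs <- lapply(1:3, function(i) circle_points(24, r = 10 + i))
  st <- stack_to_3d(cs, z_start = 5, dz = 1.5)
  su <- build_surface(st, 7)
  for (i in 1:2) {
    zexp <- (1 - su$theta) * st$z[i] + su$theta * st$z[i + 1]
    expect_identical(su$bands[[i]][, , 3],
                     matrix(zexp, 7, 24))
    # contour rows appear exactly in the surface
    expect_identical(su$bands[[i]][1, , 1:2], st$points[i, , ])
    expect_identical(su$bands[[i]][7, , 1:2], st$points[i + 1, , ])
  }
  # adjacent bands share the contour row bit for bit
  expect_identical(su$bands[[1]][7, , ], su$bands[[2]][1, , ])
})

test_that("theta-derivatives on both sides of an interior contour are parallel", {
  psi <- (0:31) / 32
  u <- cbind(cos(2 * pi * psi), sin(2 * pi * psi))
  cs <- list(10 * u, 13 * u, 17 * u)
  st <- stack_to_3d(cs, 0, 1)
  v <- tangent_field(st)
  h <- 1e-7
  b1 <- blend_band(st$points[1, , ], st$points[2, , ], v[1, , ], v[2, , ],
                   0, 1, theta = c(1 - h, 1))
  b2 <- blend_band(st$points[2, , ], st$points[3, , ], v[2, , ], v[3, , ],
                   1, 2, theta = c(0, h))
  for (j in c(1, 9, 20)) {
    below <- c((b1[2, j, ] - b1[1, j, ]) / h, 1)  # (dB/dtheta, dz/dtheta=dz)
    above <- c((b2[2, j, ] - b2[1, j, ]) / h, 1)
    below <- below / sqrt(sum(below^2))
    above <- above / sqrt(sum(above^2))
    # both proportional to (v^2, 1)
    expect_equal(below, above, tolerance = 1e-6)
    vv <- c(v[2, j, ], 1)
    expect_equal(below, vv / sqrt(sum(vv^2)), tolerance = 1e-5)
  }
})

test_that("meshing produces the expected counts, orientation and topology", {
  sq <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  st <- stack_to_3d(list(sq, sq), 0, 1)
  mesh <- surface_to_mesh(build_surface(st, 2))
  expect_equal(nrow(mesh$triangles), 8L)  # 4 quads x 2
  expect_equal(nrow(mesh$vertices), 8L)
  # Euler characteristic of a closed band (annulus): V - E + F = 0
  ed <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
              mesh$triangles[, c(3, 1)])
  ed <- unique(t(apply(ed, 1, sort)))
  expect_equal(nrow(mesh$vertices) - nrow(ed) + nrow(mesh$triangles), 0L)
  # cylinder mesh: all vertices at the cylinder radius
  circ <- circle_points(40, r = 12)
  mc <- surface_to_mesh(build_surface(stack_to_3d(list(circ, circ), 0, 1),
                                      5))
  expect_lt(max(abs(sqrt(mc$vertices[, 1]^2 + mc$vertices[, 2]^2) - 12)),
            1e-9)
  # outward orientation: normals point away from the axis
  tri <- mc$triangles[1, ]
  a <- mc$vertices[tri[1], ]; b <- mc$vertices[tri[2], ]
  cc <- mc$vertices[tri[3], ]
  nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
           (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
           (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
  centroid <- (a + b + cc) / 3
  expect_gt(sum(nrm[1:2] * centroid[1:2]), 0)
})

test_that("degenerate cells are collapsed, not emitted", {
  # two identical single-point 'contours' repeated: all quads degenerate
  p <- rbind(c(0, 0), c(0, 0), c(1, 0))
  st <- stack_to_3d(list(p, p), 0, 1)
  expect_message(mesh <- surface_to_mesh(build_surface(st, 2),
                                         closed = FALSE),
                 "degenerate")
  expect_true(all(apply(mesh$triangles, 1, function(tr) {
    u <- mesh$vertices[tr[2], ] - mesh$vertices[tr[1], ]
    w <- mesh$vertices[tr[3], ] - mesh$vertices[tr[1], ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sum(cr^2) > 0
  })))
})

test_that("STL and OBJ writers emit well-formed files", {
  circ <- circle_points(12, r = 4)
  mesh <- surface_to_mesh(build_surface(stack_to_3d(list(circ, circ), 0, 1),
                                        3))
  stl <- tempfile(fileext = ".stl")
  write_stl(mesh, stl)
  expect_equal(file.size(stl), 84 + 50 * nrow(mesh$triangles))
  v <- read_stl_vertices(stl)
  expect_equal(nrow(v), 3 * nrow(mesh$triangles))
  expect_lt(max(abs(sqrt(v[, 1]^2 + v[, 2]^2) - 4)), 1e-5)  # float32
  obj <- tempfile(fileext = ".obj")
  write_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$triangles))
})
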