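test_that("Hermite basis matches the defining polynomials", {
  expect_equal(unname(hermite_basis(0)), matrix(c(1, 0, 0, 0), 1))
  expect_equal(unname(hermite_basis(1)), matrix(c(0, 1, 0, 0), 1))
  expect_equal(unname(hermite_basis(0.5)), matrix(c(0.5, 0.5, 0.125, -0.125), 1))
  expect_error(hermite_basis(1.2), "\\[0, 1\\]")
  expect_error(hermite_basis(-0.1), "\\[0, 1\\]")
})

test_that("basis partition of unity and tangent-term endpoint vanishing", {
  s <- withr::with_seed(42, runif(1000))
  H <- hermite_basis(s)
  expect_equal(H[, 1] + H[, 2], rep(1, 1000), tolerance = 1e-14)
  H01 <- hermite_basis(c(0, 1))
  expect_equal(unname(H01[, 3]), c(0, 0))
  expect_equal(unname(H01[, 4]), c(0, 0))
})

test_that("control-point allocation follows the length bands, capped at 30", {
  expect_identical(allocate_control_points(25), 6L)
  expect_identical(allocate_control_points(80), 10L)
  expect_identical(allocate_control_points(170), 20L)
  expect_identical(allocate_control_points(500), 30L)
  lens <- c(seq(0.5, 400, by = 0.5), 1e6)
  counts <- allocate_control_points(lens)
  expect_true(all(counts %in% c(6L, 10L, 20L, 30L)))
  expect_true(all(counts >= 6L & counts <= 30L))
  # step function: monotone non-decreasing in length
  expect_true(all(diff(counts) >= 0))
  expect_error(allocate_control_points(0), "positive")
  expect_error(allocate_control_points(-5), "positive")
})

test_that("subsampling places control points at equal arc spacing on the polyline", {
  sq <- square_contour(side = 10)  # perimeter 40
  cps <- subsample_control_points(sq, 4)
  expect_equal(cps$points, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
               ignore_attr = TRUE)
  cc <- circle_contour(c(0, 0), 50, n = 500)
  cps <- subsample_control_points(cc, 20)
  gaps <- sqrt(rowSums((cps$points[c(2:20, 1), ] - cps$points)^2))
  # equal chord lengths within one input-polyline segment length
  seg_in <- arc_length(cc) / 500
  expect_lt(max(gaps) - min(gaps), seg_in)
  # default count comes from the allocation rule and respects the cap
  expect_lte(nrow(subsample_control_points(cc)$points), 30)
  expect_error(subsample_control_points(sq, 31), "30")
})

test_that("Catmull-Rom tangents equal centered differences of neighbors", {
  pts <- withr::with_seed(7, matrix(runif(24, 0, 100), ncol = 2))
  tg <- estimate_tangents(pts, closed = TRUE)
  n <- nrow(pts)
  for (i in seq_len(n)) {   # independent cyclic loop
    ip <- if (i == n) 1 else i + 1
    im <- if (i == 1) n else i - 1
    expect_equal(unname(tg[i, ]), unname((pts[ip, ] - pts[im, ]) / 2))
  }
  # symmetry: collinear equally spaced points give the unit step tangent
  tg3 <- estimate_tangents(rbind(c(0, 0), c(1, 0), c(2, 0)), closed = FALSE)
  expect_equal(unname(tg3[2, ]), c(1, 0))
  # regular polygon: tangents perpendicular to the radius (circle tangent)
  hex <- circle_contour(c(0, 0), 5, n = 6)
  tgh <- estimate_tangents(hex$points, closed = TRUE)
  dots <- rowSums(tgh * hex$points)
  expect_equal(dots, rep(0, 6), tolerance = 1e-12)
})

test_that("curve evaluation: sample counts, interpolation, segment expansion", {
  pts <- withr::with_seed(11, matrix(runif(16, 0, 50), ncol = 2))
  cps <- control_point_set(pts)
  for (ds in c(0.5, 0.25, 0.2, 0.1)) {
    crv <- evaluate_curve(cps, curve_sampling_params(ds))
    expect_identical(nrow(crv$points), as.integer(nrow(pts) / ds))
  }
  # ten points per segment at the default step
  crv <- evaluate_curve(cps)
  expect_identical(nrow(crv$points), 80L)
  # the curve passes through every control point exactly (s = 0 samples)
  starts <- crv$points[seq(1, 80, by = 10), ]
  expect_identical(starts, cps$points)
  # hand expansion of one segment at s in {0, 0.5}: samples 1 and 6
  P0 <- cps$points[1, ]; P1 <- cps$points[2, ]
  u0 <- cps$tangents[1, ]; u1 <- cps$tangents[2, ]
  expect_equal(unname(crv$points[1, ]), unname(P0))
  expect_equal(unname(crv$points[6, ]),
               unname(0.5 * P0 + 0.5 * P1 + 0.125 * u0 - 0.125 * u1),
               tolerance = 1e-14)
  # affine invariance: collinear points + collinear tangents stay on the line
  lin <- control_point_set(rbind(c(0, 0), c(1, 0), c(3, 0)),
                           tangents = rbind(c(1, 0), c(1, 0), c(1, 0)))
  crv_lin <- evaluate_curve(lin)
  expect_equal(crv_lin$points[, 2], rep(0, 30), tolerance = 1e-14)
})

test_that("delta_s is validated", {
  expect_error(curve_sampling_params(0), "delta_s")
  expect_error(curve_sampling_params(0.6), "delta_s")
  expect_error(curve_sampling_params(0.3), "delta_s")  # 1/0.3 not integer
})

test_that("moving a control point only changes its four adjacent segments", {
  pts <- circle_contour(c(50, 50), 30, n = 20)$points
  cps <- control_point_set(pts)
  crv0 <- evaluate_curve(cps)
  # no-op move leaves the curve identical
  expect_identical(evaluate_curve(move_control_point(cps, 5, pts[5, ]))$points,
                   crv0$points)
  j <- 8
  cps2 <- move_control_point(cps, j, pts[j, ] + c(0, 2.5))
  crv2 <- evaluate_curve(cps2)
  m <- 10
  affected <- sort(unique((seq(j - 2, j + 1) - 1) %% 20 + 1))
  for (i in setdiff(1:20, affected)) {
    rows <- ((i - 1) * m + 1):(i * m)
    expect_identical(crv2$points[rows, ], crv0$points[rows, ])
  }
  for (i in affected) {
    rows <- ((i - 1) * m + 1):(i * m)
    expect_false(isTRUE(all.equal(crv2$points[rows, ], crv0$points[rows, ])))
  }
  # affected segments match a from-scratch fit of the displaced polygon
  scratch <- evaluate_curve(control_point_set(cps2$points))
  expect_identical(crv2$points, scratch$points)
  expect_error(move_control_point(cps, 0, c(0, 0)), "index")
  expect_error(move_control_point(cps, 21, c(0, 0)), "index")
})
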