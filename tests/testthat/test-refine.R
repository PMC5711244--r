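test_that("normal estimation: collinear cases and the PCA oracle", {
  n1 <- estimate_normal(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(abs(n1), c(0, 1))
  n2 <- estimate_normal(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(abs(n2), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
  expect_equal(sum(n2 * c(1, 1)), 0, tolerance = 1e-12)
  # random non-collinear triples: normal is perpendicular to the TLS line
  for (i in 1:20) {
    pts <- withr::with_seed(200 + i, matrix(runif(6, 0, 10), 3, 2))
    nr <- estimate_normal(pts[1, ], pts[2, ], pts[3, ])
    C <- crossprod(sweep(pts, 2, colMeans(pts)))
    tls <- eigen(C, symmetric = TRUE)$vectors[, 1]
    expect_equal(abs(sum(nr * tls)), 0, tolerance = 1e-10)
    expect_equal(sqrt(sum(nr^2)), 1, tolerance = 1e-12)
  }
  expect_error(estimate_normal(c(1, 1), c(2, 2), c(1, 1)), "coincide")
})

test_that("refine_point: flat field fixed point, step edge, argmax stability", {
  flat <- compute_gradient(matrix(3, 20, 20), 1)
  p <- c(9.3, 10.7)
  expect_equal(unname(refine_point(flat, c(8, 10), p, c(10, 11))), p)
  # point 1 px off a vertical step edge, horizontal normal: the result is
  # within delta_d of the dense line-search maximum of the sampled field
  sc <- make_step_edge(size = c(40, 40), edge_x = 20.4)
  f <- compute_gradient(sc$image, 1)
  prm <- refinement_params(d = 2, delta_d = 0.1)
  got <- refine_point(f, c(19.4, 19), c(19.4, 20), c(19.4, 21), prm)
  tg <- seq(17.4, 21.4, by = 0.001)
  dense <- tg[which.max(sample_magnitude(f, tg, rep(20, length(tg))))]
  expect_lt(abs(got[1] - dense), prm$delta_d)
  expect_equal(unname(got[2]), 20)
  # a point already at its segment argmax stays put
  again <- refine_point(f, got + c(0, -1), got, got + c(0, 1), prm)
  expect_equal(unname(again), unname(got))
})

test_that("refine_point equals exhaustive candidate enumeration on 100 random fields", {
  for (i in 1:100) {
    dat <- withr::with_seed(3000 + i, {
      img <- matrix(runif(16 * 16, 0, 255), 16, 16)
      p <- runif(2, 4, 11)
      th <- runif(1, 0, 2 * pi)
      list(img = img, p = p, prev = p + c(cos(th), sin(th)),
           nxt = p - c(cos(th), sin(th)),
           d = sample(1:3, 1), dd = sample(c(0.1, 0.25, 0.5), 1))
    })
    f <- compute_gradient(dat$img, 0.8)
    prm <- refinement_params(dat$d, dat$dd)
    got <- refine_point(f, dat$prev, dat$p, dat$nxt, prm)
    nrm <- estimate_normal(dat$prev, dat$p, dat$nxt)
    want <- oracle_refine_point(f, dat$p, nrm, dat$d, dat$dd)
    expect_identical(unname(got), want)
  }
})

test_that("every refined point stays within d of its input point", {
  for (i in 1:50) {
    cfg <- withr::with_seed(4000 + i, {
      list(img = matrix(runif(32 * 32, 0, 255), 32, 32),
           ctr = c(runif(1, 12, 19), runif(1, 12, 19)),
           r = runif(1, 5, 9), d = sample(1:4, 1))
    })
    f <- compute_gradient(cfg$img, 1)
    crv <- circle_contour(cfg$ctr, cfg$r, n = 24)
    prm <- refinement_params(cfg$d, 0.1)
    out <- refine_curve(crv, f, prm)
    disp <- sqrt(rowSums((out$points - crv$points)^2))
    expect_lte(max(disp), cfg$d + 1e-9)
  }
})

test_that("refinement is idempotent up to the candidate grid", {
  sc <- make_noisy_disc(size = c(128, 128), radius = 40, noise_sigma = 5, seed = 9)
  f <- compute_gradient(sc$image, 1)
  prm <- refinement_params(2, 0.1)
  r1 <- refine_curve(perturb_contour(sc$truth_contour, 0.8, seed = 10), f, prm)
  r2 <- refine_curve(r1, f, prm)
  disp <- sqrt(rowSums((r2$points - r1$points)^2))
  expect_lte(max(disp), 2 * prm$delta_d)
})

test_that("refinement pulls a perturbed contour toward the true disc boundary", {
  sc <- make_noisy_disc(noise_sigma = 10, seed = 21)
  init <- perturb_contour(sc$truth_contour, 1, seed = 22)
  f <- compute_gradient(sc$image, 1)
  out <- refine_curve(init, f, refinement_params())
  expect_identical(nrow(out$points), nrow(init$points))
  e_in <- mean_boundary_distance(init, sc$truth_contour)
  e_out <- mean_boundary_distance(out, sc$truth_contour)
  expect_lt(e_out, e_in)
  expect_lt(e_out, 0.5)
})

test_that("refinement parameter validation", {
  expect_error(refinement_params(d = 0.5), "between 1 and 5")
  expect_error(refinement_params(d = 6), "between 1 and 5")
  expect_error(refinement_params(delta_d = 0), "delta_d")
  expect_error(refinement_params(d = 1, delta_d = 2), "delta_d")
  expect_error(refinement_params(tie_policy = "bogus"))
  # keep_original: the point survives ties with its own magnitude
  flat <- compute_gradient(matrix(1, 12, 12), 1)
  p <- c(5.2, 6.1)
  keep <- refinement_params(2, 0.5, "keep_original")
  expect_equal(unname(refine_point(flat, c(4, 6), p, c(6, 6), keep)), p)
})
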