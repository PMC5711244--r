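#' Synthetic test scenes with analytic ground truth
#'
#' Generators for the phantom images used throughout the tests: a dark disc
#' on a bright background corrupted by additive Gaussian noise (the
#' standard circle phantom for boundary-accuracy experiments), and a
#' vertical step edge at a subpixel column (a unit-test fixture for the
#' refinement stage). Boundaries are anti-aliased by area coverage, so the
#' true edge has a well-defined subpixel gradient maximum. All scenes are
#' reproducible: the same `(parameters, seed)` yield bitwise-identical
#' images, and the caller's RNG state is never disturbed.
#'
#' @param size `(rows, cols)` image size; default `c(256, 256)`.
#' @param center disc center `(x, y)` in 0-based pixel coordinates;
#'   default the image center.
#' @param radius disc radius in pixels (default 85); the disc (including
#'   its 1-px anti-aliased rim) must fit inside the image.
#' @param fg,bg foreground (inside) and background intensities; defaults
#'   0 (black disc) and 255.
#' @param noise_sigma standard deviation of the additive Gaussian noise in
#'   intensity units (default 10; 0 for a clean image).
#' @param seed RNG seed for the noise.
#' @return a `synthetic_scene` object: `image` (matrix), `truth_contour`
#'   (a dense [contour()] on the analytic boundary), `truth_params`
#'   (named list), `seed`, `noise_sigma`.
#' @examples
#' sc <- make_noisy_disc(seed = 1)
#' range(sc$image)
#' @export
make_noisy_disc <- function(size = c(256, 256),
                            center = (rev(size) - 1) / 2,
                            radius = 85, fg = 0, bg = 255,
                            noise_sigma = 10, seed = 1L) {
  stopifnot(length(size) == 2, all(size >= 3), radius > 0, noise_sigma >= 0)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  cx <- center[1]; cy <- center[2]
  if (cx - radius < -0.5 || cx + radius > nc - 0.5 ||
      cy - radius < -0.5 || cy + radius > nr - 0.5)
    stop("disc exceeds image bounds", call. = FALSE)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  dist <- sqrt((x - cx)^2 + (y - cy)^2)
  # area-coverage anti-aliasing: fraction of the unit pixel inside the
  # disc, boundary locally straight -> linear ramp of width 1 px
  coverage <- clamp(radius - dist + 0.5, 0, 1)
  clean <- bg + (fg - bg) * coverage
  img <- if (noise_sigma > 0) {
    with_seed(seed, clean + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc))
  } else clean
  structure(list(image = img,
                 truth_contour = circle_contour(c(cx, cy), radius),
                 truth_params = list(shape = "disc", center = c(cx, cy),
                                     radius = radius, fg = fg, bg = bg),
                 seed = seed, noise_sigma = noise_sigma),
            class = "synthetic_scene")
}

#' @rdname make_noisy_disc
#' @param edge_x subpixel column of the vertical edge, in
#'   `(0, cols - 1)`; intensities are `bg` left of the edge and `fg` right
#'   of it, with area-coverage blending in the pixel(s) the edge crosses.
#' @export
make_step_edge <- function(size = c(64, 64), edge_x = 31.5, fg = 255, bg = 0,
                           noise_sigma = 0, seed = 1L) {
  stopifnot(length(size) == 2, all(size >= 3), noise_sigma >= 0)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  if (edge_x <= 0 || edge_x >= nc - 1)
    stop("edge_x must be strictly inside (0, cols - 1)", call. = FALSE)
  xs <- 0:(nc - 1)
  # fraction of pixel footprint [x - 0.5, x + 0.5] right of the edge
  coverage <- clamp(xs + 0.5 - edge_x, 0, 1)
  clean <- matrix(bg + (fg - bg) * coverage, nr, nc, byrow = TRUE)
  img <- if (noise_sigma > 0) {
    with_seed(seed, clean + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc))
  } else clean
  ys <- seq(0, nr - 1, length.out = max(nr, 16L))
  structure(list(image = img,
                 truth_contour = NULL,
                 truth_params = list(shape = "step_edge", edge_x = edge_x,
                                     fg = fg, bg = bg),
                 truth_line = cbind(x = rep(edge_x, length(ys)), y = ys),
                 seed = seed, noise_sigma = noise_sigma),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s, %d x %d, noise sigma %g, seed %s\n",
              x$truth_params$shape, nrow(x$image), ncol(x$image),
              x$noise_sigma, format(x$seed)))
  invisible(x)
}

#' Perturb a contour along its normals
#'
#' Displaces each point along its local (centered-difference) normal by
#' smooth, spatially correlated noise whose maximum absolute displacement
#' equals `amplitude`. Emulates the imprecision of a hand-drawn boundary:
#' errors of a human tracing are smooth along the curve, not independent
#' per point.
#'
#' @param contour a [contour()].
#' @param amplitude maximum normal displacement in pixels (`>= 0`; 0
#'   returns the contour unchanged).
#' @param seed RNG seed.
#' @param smoothness circular smoothing window as a fraction of the number
#'   of points (default 0.05).
#' @return a perturbed [contour()] with the same number of points.
#' @export
perturb_contour <- function(contour, amplitude, seed = 1L, smoothness = 0.05) {
  stopifnot(inherits(contour, "contour"), amplitude >= 0)
  if (amplitude == 0) return(contour)
  pts <- contour$points
  n <- nrow(pts)
  raw <- with_seed(seed, stats::rnorm(n))
  # circular moving-average smoothing for along-curve correlation
  w <- max(3L, 2L * ceiling(smoothness * n / 2) + 1L)
  h <- (w - 1L) %/% 2L
  wrapped <- raw[((0:(n + 2L * h - 1L) - h) %% n) + 1L]
  disp <- stats::filter(wrapped, rep(1 / w, w), sides = 2)[(h + 1L):(h + n)]
  disp <- as.numeric(disp)
  mx <- max(abs(disp))
  if (mx > 0) disp <- disp * (amplitude / mx)
  tang <- estimate_tangents(pts, closed = TRUE)
  nrm <- cbind(-tang[, 2], tang[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  contour(pts + disp * nrm)
}
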