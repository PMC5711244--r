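#' Sampled Gaussian and Gaussian-derivative kernels
#'
#' Samples the 1D Gaussian \eqn{G(x) = \frac{1}{\sqrt{2\pi}\sigma}
#' e^{-x^2/2\sigma^2}} and its derivative \eqn{G'(x) = -\frac{x}{\sigma^2}
#' G(x)} at integer offsets `-r..r` with `r = ceil(truncate * sigma)`. The
#' smoothing kernel is normalized to sum 1; the derivative kernel is exactly
#' antisymmetric (so it sums to 0 after mean removal, and responds 0 to a
#' constant image).
#'
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @param truncate kernel support in standard deviations (default 4).
#' @return list with `smooth`, `deriv` (numeric vectors of length `2r + 1`)
#'   and `offsets` (`-r:r`).
#' @export
gaussian_derivative_kernels <- function(sigma, truncate = 4) {
  stop_if_not_scalar(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- ceiling(truncate * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  # bitwise antisymmetric by construction (g depends on x^2 only), so the
  # kernel sums to zero without any mean correction
  d <- -x / sigma^2 * g
  list(smooth = g / sum(g), deriv = d, offsets = x)
}

# Pad a matrix by `r` rows/cols of reflection (edge value repeated), then
# correlate each row / each column with kernel k (odd length 2r+1).
reflect_index <- function(n, r) c(r:1, 1:n, n:(n - r + 1L))

# Mirrored taps are accumulated pairwise so that an antisymmetric kernel
# cancels *exactly* on locally constant data (a flat image then yields a
# bitwise-zero gradient, keeping tie-handling in the refinement exact).
correlate_cols <- function(img, k) {
  # 1D correlation along x (across columns), reflective boundary
  r <- (length(k) - 1L) %/% 2L
  nc <- ncol(img)
  pad <- img[, reflect_index(nc, r), drop = FALSE]
  ctr <- r + 1L
  out <- k[ctr] * pad[, ctr:(ctr + nc - 1L), drop = FALSE]
  for (j in seq_len(r)) {
    left <- pad[, (ctr - j):(ctr - j + nc - 1L), drop = FALSE]
    right <- pad[, (ctr + j):(ctr + j + nc - 1L), drop = FALSE]
    out <- out + (k[ctr - j] * left + k[ctr + j] * right)
  }
  out
}

correlate_rows <- function(img, k) {
  # 1D correlation along y (across rows), reflective boundary
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img)
  pad <- img[reflect_index(nr, r), , drop = FALSE]
  ctr <- r + 1L
  out <- k[ctr] * pad[ctr:(ctr + nr - 1L), , drop = FALSE]
  for (j in seq_len(r)) {
    up <- pad[(ctr - j):(ctr - j + nr - 1L), , drop = FALSE]
    down <- pad[(ctr + j):(ctr + j + nr - 1L), , drop = FALSE]
    out <- out + (k[ctr - j] * up + k[ctr + j] * down)
  }
  out
}

#' Gaussian-derivative gradient field
#'
#' Computes per-pixel image gradients by separable filtering: the horizontal
#' component `gx` is the derivative-of-Gaussian along x with Gaussian
#' smoothing along y, and symmetrically for `gy`; the edge-strength map is
#' `magnitude = sqrt(gx^2 + gy^2)`. Smoothing suppresses noise before
#' differentiation; `sigma` controls the trade-off (larger for
#' low-resolution or noisy images). Boundaries are handled by reflection.
#'
#' @param image numeric matrix (rows x cols) of intensities, at least 3x3.
#' @param sigma Gaussian scale in pixels (default 1).
#' @param truncate kernel support in standard deviations (default 4).
#' @return a `gradient_field` object with elements `gx`, `gy`, `magnitude`
#'   (matrices), `sigma`, `shape = c(rows, cols)`, `nms_applied = FALSE`.
#' @export
compute_gradient <- function(image, sigma = 1, truncate = 4) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  k <- gaussian_derivative_kernels(sigma, truncate)
  # true derivative: convolution with G' == correlation with reversed G'
  dk <- rev(k$deriv)
  gx <- correlate_rows(correlate_cols(image, dk), k$smooth)
  gy <- correlate_cols(correlate_rows(image, dk), k$smooth)
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
                 sigma = sigma, shape = dim(image), nms_applied = FALSE),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d, sigma = %g, nms %s\n",
              x$shape[1], x$shape[2], x$sigma,
              if (x$nms_applied) "applied" else "not applied"))
  invisible(x)
}

#' Non-maximal suppression of gradient magnitude
#'
#' Thins edge responses Canny-style: the magnitude at a pixel is kept only
#' if it is at least as large as the magnitude interpolated (linearly
#' between the two nearest 8-neighbors) one step along the gradient
#' direction on both sides. `gx`/`gy` are left untouched. Useful for
#' visualizing distinct boundaries; the subpixel refinement deliberately
#' samples the unsuppressed field (see [refine_curve()]).
#'
#' @param field a [compute_gradient()] result with `nms_applied = FALSE`.
#' @return a `gradient_field` with thinned `magnitude` and
#'   `nms_applied = TRUE`.
#' @export
nonmax_suppression <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  if (field$nms_applied) stop("non-maximal suppression already applied", call. = FALSE)
  m <- field$magnitude
  nr <- nrow(m); nc <- ncol(m)
  # pad by edge replication; shifts bring each 8-neighbor onto the pixel
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  P[1L, ] <- P[2L, ]; P[nr + 2L, ] <- P[nr + 1L, ]
  P[, 1L] <- P[, 2L]; P[, nc + 2L] <- P[, nc + 1L]
  sh <- function(dy, dx) P[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx)]
  E <- sh(0L, 1L); W <- sh(0L, -1L); S <- sh(1L, 0L); N <- sh(-1L, 0L)
  SE <- sh(1L, 1L); NW <- sh(-1L, -1L); NE <- sh(-1L, 1L); SW <- sh(1L, -1L)
  gx <- field$gx; gy <- field$gy
  ax <- abs(gx); ay <- abs(gy)
  horiz <- ax >= ay
  # fraction toward the diagonal neighbor
  w <- ifelse(horiz, ifelse(ax > 0, ay / ax, 0), ifelse(ay > 0, ax / ay, 0))
  samesign <- (gx * gy) >= 0
  # step (+) along gradient and (-) against it, bilinear between neighbors
  p1 <- ifelse(horiz,
               (1 - w) * E + w * ifelse(samesign, SE, NE),
               (1 - w) * S + w * ifelse(samesign, SE, SW))
  p2 <- ifelse(horiz,
               (1 - w) * W + w * ifelse(samesign, NW, SW),
               (1 - w) * N + w * ifelse(samesign, NW, NE))
  keep <- (m >= p1) & (m >= p2) & (m > 0)
  field$magnitude <- ifelse(keep, m, 0)
  field$nms_applied <- TRUE
  field
}

# Bilinear interpolation on a matrix at 0-based (x = col, y = row)
# coordinates; callers guarantee 0 <= x <= nc-1, 0 <= y <= nr-1.
bilinear_sample <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  x0 <- pmin(floor(x), nc - 2L); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), nr - 2L); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L   # 1-based matrix indices
  idx <- cbind(i, j)
  v00 <- mat[idx]
  v01 <- mat[cbind(i, j + 1L)]
  v10 <- mat[cbind(i + 1L, j)]
  v11 <- mat[cbind(i + 1L, j + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Subpixel gradient-magnitude sampling
#'
#' Bilinear interpolation of the magnitude map at subpixel positions; exact
#' array values at integer coordinates. This is what gives the refinement
#' its subpixel localization.
#'
#' @param field a [compute_gradient()] result.
#' @param x,y 0-based subpixel coordinates (vectors allowed), inside
#'   `[0, cols - 1] x [0, rows - 1]`.
#' @return numeric vector of interpolated magnitudes.
#' @export
sample_magnitude <- function(field, x, y) {
  stopifnot(inherits(field, "gradient_field"))
  nrw <- field$shape[1]; ncl <- field$shape[2]
  if (any(x < 0 | x > ncl - 1 | y < 0 | y > nrw - 1))
    stop("sample position outside image bounds", call. = FALSE)
  bilinear_sample(field$magnitude, x, y)
}
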