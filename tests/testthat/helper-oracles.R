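# Independent oracle implementations used by several test files. These are
# deliberately written as plain loops, sharing no code with the package.

# Brute-force 2D convolution-style correlation of `img` with the separable
# outer-product kernel ky %o% kx, reflective boundary (edge repeated),
# matching the package's padding convention.
brute_force_correlate2d <- function(img, ky, kx) {
  ry <- (length(ky) - 1) / 2
  rx <- (length(kx) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (dy in -ry:ry) for (dx in -rx:rx) {
      acc <- acc + ky[dy + ry + 1] * kx[dx + rx + 1] *
        img[refl(r + dy, nr), refl(c + dx, nc)]
    }
    out[r, c] <- acc
  }
  out
}

# Independent bilinear interpolation at 0-based (x, y).
oracle_bilinear <- function(mat, x, y) {
  x0 <- min(max(floor(x), 0), ncol(mat) - 2)
  y0 <- min(max(floor(y), 0), nrow(mat) - 2)
  fx <- x - x0; fy <- y - y0
  v00 <- mat[y0 + 1, x0 + 1]; v01 <- mat[y0 + 1, x0 + 2]
  v10 <- mat[y0 + 2, x0 + 1]; v11 <- mat[y0 + 2, x0 + 2]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Exhaustive normal-search refinement of a single point: enumerate every
# candidate with a plain loop, drop out-of-bounds ones, pick the maximum
# with the nearest-to-original tie rule (original wins exact ties,
# negative side preferred on symmetric ties).
oracle_refine_point <- function(field, p, normal, d, delta_d) {
  k <- floor(d / delta_d + 1e-9)
  best_val <- -Inf; best_t <- NA
  for (i in -k:k) {
    t <- i * delta_d
    cx <- p[1] + t * normal[1]
    cy <- p[2] + t * normal[2]
    if (cx < 0 || cx > field$shape[2] - 1 || cy < 0 || cy > field$shape[1] - 1)
      next
    v <- oracle_bilinear(field$magnitude, cx, cy)
    better <- v > best_val ||
      (v == best_val && (abs(t) < abs(best_t) ||
                         (abs(t) == abs(best_t) && t < best_t)))
    if (better) { best_val <- v; best_t <- t }
  }
  if (!is.finite(best_val)) stop("all candidates out of bounds")
  c(p[1] + best_t * normal[1], p[2] + best_t * normal[2])
}

# Brute-force all-pairs point-to-segment minimum distance from each row of
# P to the closed polyline Q.
oracle_points_to_polyline <- function(P, Q) {
  m <- nrow(Q)
  sapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    best <- Inf
    for (j in seq_len(m)) {
      a <- Q[j, ]; b <- Q[if (j == m) 1 else j + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) min(max(sum((p - a) * ab) / len2, 0), 1) else 0
      best <- min(best, sqrt(sum((p - a - t * ab)^2)))
    }
    best
  })
}

# A square boundary as a densely sampled polyline (perimeter 4 * side).
square_contour <- function(side = 10, per_edge = 25) {
  t <- seq(0, side, length.out = per_edge + 1)[-(per_edge + 1)]
  contour(rbind(cbind(t, 0), cbind(side, t), cbind(side - t, side), cbind(0, side - t)))
}
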