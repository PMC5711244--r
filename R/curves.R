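#' Hermite basis functions
#'
#' Evaluates the four cubic Hermite basis polynomials at parameter `s` in
#' the unit interval:
#' \deqn{h_1 = 2s^3 - 3s^2 + 1,\quad h_2 = -2s^3 + 3s^2,\quad
#'       h_3 = s^3 - 2s^2 + s,\quad h_4 = s^3 - s^2.}
#' `h1` and `h2` weight the segment endpoints, `h3` and `h4` the endpoint
#' tangents; `h1 + h2 == 1` for every `s` (partition of unity), so the
#' interpolant is affine-invariant.
#'
#' @param s numeric vector of parameters, each in `[0, 1]`.
#' @return a length-`s` x 4 matrix with columns `h1..h4`.
#' @examples
#' hermite_basis(0)    # 1 0 0 0
#' hermite_basis(0.5)  # 0.5 0.5 0.125 -0.125
#' @export
hermite_basis <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s))) stop("s must be finite numeric", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]", call. = FALSE)
  s2 <- s * s
  s3 <- s2 * s
  cbind(h1 = 2 * s3 - 3 * s2 + 1,
        h2 = -2 * s3 + 3 * s2,
        h3 = s3 - 2 * s2 + s,
        h4 = s3 - s2)
}

#' Allocate control points by boundary length
#'
#' The number of control points offered for revision is a step function of
#' the boundary arc length: short boundaries still get enough points to shape
#' small regions, long boundaries are capped at 30 so manual revision stays
#' tractable. Bands: length < 30 px gives 6 points, 30--150 px gives 10,
#' 150--200 px gives 20, and 200 px or more gives 30 (left-closed intervals).
#'
#' @param boundary_length positive arc length in pixels.
#' @return integer count in `[6, 30]`.
#' @examples
#' allocate_control_points(c(25, 80, 170, 500))  # 6 10 20 30
#' @export
allocate_control_points <- function(boundary_length) {
  if (!is.numeric(boundary_length) || any(!is.finite(boundary_length)) ||
      any(boundary_length <= 0))
    stop("boundary_length must be positive", call. = FALSE)
  out <- ifelse(boundary_length < 30, 6L,
         ifelse(boundary_length < 150, 10L,
         ifelse(boundary_length < 200, 20L, 30L)))
  as.integer(out)
}

#' Control-point sets
#'
#' A `control_point_set` holds the sparse points `P_i` interpolated by the
#' fitted closed curve, together with one tangent vector `u_i` per point.
#' Tangents use the Catmull-Rom centered-difference rule
#' `u_i = (P_{i+1} - P_{i-1}) / 2` with cyclic indexing, which gives the
#' smooth interpolating behavior and local control the revision workflow
#' relies on.
#'
#' @param points `n x 2` matrix of `(x, y)`, `3 <= n <= 30`.
#' @param tangents optional `n x 2` matrix of tangent vectors; estimated
#'   with [estimate_tangents()] when omitted.
#' @return an object of class `control_point_set` with elements `points`,
#'   `tangents`, `closed` (always `TRUE`).
#' @export
control_point_set <- function(points, tangents = NULL) {
  points <- as_points_matrix(points)
  n <- nrow(points)
  if (n < 3L || n > 30L)
    stop("control point sets must have between 3 and 30 points", call. = FALSE)
  if (is.null(tangents)) tangents <- estimate_tangents(points, closed = TRUE)
  tangents <- as_points_matrix(tangents)
  if (nrow(tangents) != n)
    stop("tangents must match points in number", call. = FALSE)
  structure(list(points = points, tangents = tangents, closed = TRUE),
            class = "control_point_set")
}

#' @export
print.control_point_set <- function(x, ...) {
  cat(sprintf("<control_point_set> %d points, closed\n", nrow(x$points)))
  invisible(x)
}

#' Catmull-Rom tangent estimation
#'
#' Centered-difference tangents `u_i = (P_{i+1} - P_{i-1}) / 2`. For closed
#' curves the indexing is cyclic; for open point lists the ends are clamped
#' to one-sided differences.
#'
#' @param points `n x 2` matrix, `n >= 3`.
#' @param closed treat the list as a closed loop (cyclic indexing).
#' @return `n x 2` matrix of tangent vectors.
#' @export
estimate_tangents <- function(points, closed = TRUE) {
  points <- as_points_matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (closed) {
    nxt <- points[c(2:n, 1L), , drop = FALSE]
    prv <- points[c(n, 1:(n - 1L)), , drop = FALSE]
    (nxt - prv) / 2
  } else {
    tang <- matrix(0, n, 2)
    tang[2:(n - 1L), ] <- (points[3:n, ] - points[1:(n - 2L), ]) / 2
    tang[1L, ] <- points[2L, ] - points[1L, ]
    tang[n, ] <- points[n, ] - points[n - 1L, ]
    colnames(tang) <- c("x", "y")
    tang
  }
}

#' Uniform arc-length subsampling of a boundary
#'
#' Places `count` control points on the input closed polyline at equal
#' arc-length spacing `arc_length(boundary) / count`, starting from the
#' first vertex. Points falling inside a polyline segment are linearly
#' interpolated, so every control point lies exactly on the input boundary.
#'
#' @param boundary a [contour()] (e.g. the raw hand-drawn boundary).
#' @param count number of control points, `3 <= count <= 30`; default from
#'   [allocate_control_points()].
#' @return a [control_point_set()] with Catmull-Rom tangents.
#' @export
subsample_control_points <- function(boundary,
                                     count = allocate_control_points(arc_length(boundary))) {
  stopifnot(inherits(boundary, "contour"))
  count <- as.integer(count)
  if (count < 3L) stop("count must be at least 3", call. = FALSE)
  pts <- boundary$points
  n <- nrow(pts)
  seg <- segment_lengths(pts)
  L <- sum(seg)
  # distinct arc positions require spacing > 0
  if (count > 30L) stop("count must not exceed 30", call. = FALSE)
  targets <- (0:(count - 1L)) * L / count
  cum <- c(0, cumsum(seg))          # arc position of each vertex, vertex n+1 == start
  idx <- findInterval(targets, cum, rightmost.closed = FALSE)
  idx <- pmin(idx, n)               # guard exact L (cannot happen: targets < L)
  frac <- (targets - cum[idx]) / seg[idx]
  a <- pts[idx, , drop = FALSE]
  b <- pts[c(2:n, 1L), , drop = FALSE][idx, , drop = FALSE]
  cp <- a + frac * (b - a)
  if (any(sqrt(rowSums((cp - cp[c(2:count, 1L), , drop = FALSE])^2)) == 0))
    stop("count exceeds the number of resolvable positions on this boundary",
         call. = FALSE)
  control_point_set(cp)
}

#' Curve sampling step
#'
#' @param delta_s parameter step per segment; must satisfy
#'   `0 < delta_s <= 0.5` with `1/delta_s` a whole number, so each segment
#'   emits exactly `1/delta_s` samples. Default 0.1 (ten points per segment).
#' @return a `curve_sampling_params` object.
#' @export
curve_sampling_params <- function(delta_s = 0.1) {
  stop_if_not_scalar(delta_s, "delta_s")
  m <- 1 / delta_s
  if (delta_s <= 0 || delta_s > 0.5 || abs(m - round(m)) > 1e-9)
    stop("delta_s must be in (0, 0.5] with 1/delta_s a positive integer",
         call. = FALSE)
  structure(list(delta_s = delta_s, per_segment = as.integer(round(m))),
            class = "curve_sampling_params")
}

#' Evaluate a closed Hermite cubic curve
#'
#' Each of the `N` cyclic segments `P_i -> P_{i+1}` is the Hermite cubic
#' `P(s) = h1(s) P_i + h2(s) P_{i+1} + h3(s) u_i + h4(s) u_{i+1}` sampled at
#' `s = 0, delta_s, ..., 1 - delta_s`; the segment endpoint `s = 1` is the
#' next segment's `s = 0`, so the closed curve has exactly `N / delta_s`
#' points and passes through every control point exactly (at each segment's
#' first sample).
#'
#' @param cps a [control_point_set()].
#' @param params a [curve_sampling_params()] (or a bare `delta_s` number).
#' @return a [contour()] with `N / delta_s` points.
#' @export
evaluate_curve <- function(cps, params = curve_sampling_params()) {
  stopifnot(inherits(cps, "control_point_set"))
  if (is.numeric(params)) params <- curve_sampling_params(params)
  m <- params$per_segment
  n <- nrow(cps$points)
  s <- (0:(m - 1L)) / m
  H <- hermite_basis(s)                      # m x 4
  nxt <- c(2:n, 1L)
  out <- matrix(0, n * m, 2)
  for (i in seq_len(n)) {
    G <- rbind(cps$points[i, ], cps$points[nxt[i], ],
               cps$tangents[i, ], cps$tangents[nxt[i], ])  # 4 x 2
    out[((i - 1L) * m + 1L):(i * m), ] <- H %*% G
  }
  contour(out)
}

#' Move one control point (programmatic revision)
#'
#' Replaces the control point at `index` and re-estimates tangents. With
#' centered-difference tangents only the tangents at `index - 1`, `index`,
#' `index + 1` change, so a resampled curve differs from the original only
#' on the four cyclic segments `index - 2 .. index + 1`: revision is local.
#'
#' @param cps a [control_point_set()].
#' @param index 1-based index of the point to move.
#' @param new_pos `(x, y)` destination.
#' @return a new [control_point_set()]; the input is unchanged.
#' @export
move_control_point <- function(cps, index, new_pos) {
  stopifnot(inherits(cps, "control_point_set"))
  n <- nrow(cps$points)
  if (!is.numeric(index) || length(index) != 1L || index < 1L || index > n ||
      index != round(index))
    stop("index out of range", call. = FALSE)
  new_pos <- as.numeric(new_pos)
  if (length(new_pos) != 2L || any(!is.finite(new_pos)))
    stop("new_pos must be a finite (x, y) pair", call. = FALSE)
  pts <- cps$points
  pts[index, ] <- new_pos
  control_point_set(pts)
}
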