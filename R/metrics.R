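#' Contour accuracy metrics
#'
#' Quantitative agreement between a test contour and a reference (ground
#' truth) contour: mean absolute boundary distance, symmetric Hausdorff
#' distance, and the Dice overlap of the enclosed regions.
#'
#' Distances are point-to-polyline: for each vertex of one contour, the
#' Euclidean distance to the nearest point on any segment of the other
#' contour's closed polyline (not merely the nearest vertex), so densely
#' and sparsely sampled contours compare fairly.
#'
#' @param test,truth [contour()] objects.
#' @return `mean_boundary_distance` and `hausdorff_distance` return pixels;
#'   `dice_from_contours` returns a value in `[0, 1]`;
#'   `contour_error_report` returns a `contour_error_report` list with
#'   `mean_abs_distance`, `hausdorff`, `dice` (or `NA` when `shape` is
#'   missing), `n_points`.
#' @examples
#' a <- circle_contour(c(128, 128), 85)
#' b <- circle_contour(c(128, 128), 86)
#' mean_boundary_distance(b, a)  # 1
#' @export
mean_boundary_distance <- function(test, truth) {
  stopifnot(inherits(test, "contour"), inherits(truth, "contour"))
  mean(points_to_polyline_distance(test$points, truth$points))
}

# For each row of P, min distance to the closed polyline with vertices Q.
points_to_polyline_distance <- function(P, Q) {
  m <- nrow(Q)
  A <- Q
  B <- Q[c(2:m, 1L), , drop = FALSE]
  best <- rep(Inf, nrow(P))
  for (i in seq_len(m)) {
    ab <- B[i, ] - A[i, ]
    len2 <- sum(ab^2)
    ap_x <- P[, 1] - A[i, 1]
    ap_y <- P[, 2] - A[i, 2]
    t <- if (len2 > 0) clamp((ap_x * ab[1] + ap_y * ab[2]) / len2, 0, 1) else 0
    dx <- ap_x - t * ab[1]
    dy <- ap_y - t * ab[2]
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' @rdname mean_boundary_distance
#' @export
hausdorff_distance <- function(test, truth) {
  stopifnot(inherits(test, "contour"), inherits(truth, "contour"))
  max(max(points_to_polyline_distance(test$points, truth$points)),
      max(points_to_polyline_distance(truth$points, test$points)))
}

#' Rasterize a closed contour to a pixel mask
#'
#' Even-odd point-in-polygon test at pixel centers (0-based integer
#' coordinates).
#'
#' @param contour a [contour()].
#' @param shape `(rows, cols)` of the target mask.
#' @return logical matrix, `TRUE` inside the contour.
#' @export
rasterize_contour <- function(contour, shape) {
  stopifnot(inherits(contour, "contour"), length(shape) == 2)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  V <- contour$points
  n <- nrow(V)
  px <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  py <- matrix(0:(nr - 1), nr, nc)
  crossings <- matrix(0L, nr, nc)
  j <- n
  for (i in seq_len(n)) {
    x1 <- V[j, 1]; y1 <- V[j, 2]
    x2 <- V[i, 1]; y2 <- V[i, 2]
    if (y1 != y2) {
      hit <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crossings <- crossings + hit
    }
    j <- i
  }
  crossings %% 2L == 1L
}

#' @rdname mean_boundary_distance
#' @param shape `(rows, cols)` raster size for the overlap computation.
#' @export
dice_from_contours <- function(test, truth, shape) {
  A <- rasterize_contour(test, shape)
  B <- rasterize_contour(truth, shape)
  na <- sum(A); nb <- sum(B)
  if (na == 0L || nb == 0L)
    stop("degenerate (zero-area) contour after rasterization", call. = FALSE)
  2 * sum(A & B) / (na + nb)
}

#' @rdname mean_boundary_distance
#' @export
contour_error_report <- function(test, truth, shape = NULL) {
  structure(list(
    mean_abs_distance = mean_boundary_distance(test, truth),
    hausdorff = hausdorff_distance(test, truth),
    dice = if (is.null(shape)) NA_real_ else dice_from_contours(test, truth, shape),
    n_points = nrow(test$points)
  ), class = "contour_error_report")
}

#' @export
print.contour_error_report <- function(x, ...) {
  cat(sprintf(paste0("<contour_error_report> mean |d| = %.4f px, ",
                     "Hausdorff = %.4f px, Dice = %s, n = %d\n"),
              x$mean_abs_distance, x$hausdorff,
              if (is.na(x$dice)) "NA" else sprintf("%.4f", x$dice),
              x$n_points))
  invisible(x)
}
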