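#' Closed contour objects
#'
#' A `contour` is an ordered list of subpixel 2D points `(x, y)` in pixel
#' units tracing a closed region boundary. Coordinates follow the image
#' convention used throughout the package: `x` is the column, `y` the row,
#' pixel centers at integer coordinates, 0-based, with `(0, 0)` the top-left
#' pixel center. The closing segment (last point back to first) is implicit.
#'
#' @param points an `n x 2` matrix (or data frame / list of pairs) of
#'   `(x, y)` coordinates, `n >= 3`, no consecutive duplicates (the pair
#'   last/first counts as consecutive).
#' @return an object of class `contour` with elements `points` (matrix),
#'   `closed` (always `TRUE`) and `length` (cached arc length in pixels,
#'   including the closing segment).
#' @examples
#' sq <- contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' arc_length(sq)  # 40
#' @export
contour <- function(points) {
  points <- as_points_matrix(points)
  if (nrow(points) < 3L) stop("a contour needs at least 3 points", call. = FALSE)
  seg <- segment_lengths(points)
  if (any(seg == 0))
    stop("contour has consecutive duplicate points (zero-length segment)", call. = FALSE)
  structure(list(points = points, closed = TRUE, length = sum(seg)),
            class = "contour")
}

# Lengths of the n segments of the closed polyline (last row closes to first).
segment_lengths <- function(points) {
  nxt <- points[c(2:nrow(points), 1L), , drop = FALSE]
  sqrt(rowSums((nxt - points)^2))
}

#' @rdname contour
#' @param x a `contour`
#' @export
arc_length <- function(x) {
  stopifnot(inherits(x, "contour"))
  x$length
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, closed, arc length %.3f px\n",
              nrow(x$points), x$length))
  invisible(x)
}

#' @export
format.contour <- function(x, ...) {
  sprintf("<contour: %d pts, L=%.2f>", nrow(x$points), x$length)
}

#' Read and write contour files
#'
#' Contours are serialized either as JSON
#' (`{"closed": true, "points": [[x, y], ...]}`) or as CSV with one `x,y`
#' pair per row (header optional). The format is chosen from the file
#' extension (`.json` vs anything else).
#'
#' @param path file path.
#' @param x a [contour()] (or a control-point set, whose interpolating points
#'   are written) for `write_contour`.
#' @return `read_contour` returns a [contour()]; `write_contour` returns
#'   `path` invisibly.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    pts <- obj$points
    if (is.null(pts)) stop("JSON contour is missing a 'points' field", call. = FALSE)
    contour(as_points_matrix(pts))
  } else {
    first <- readLines(path, n = 1L)
    header <- grepl("[A-Za-z]", first)
    df <- utils::read.csv(path, header = header,
                          col.names = c("x", "y"), comment.char = "#")
    contour(as.matrix(df))
  }
}

#' @rdname read_contour
#' @export
write_contour <- function(x, path) {
  if (inherits(x, "control_point_set")) x <- contour(x$points)
  stopifnot(inherits(x, "contour"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(closed = TRUE, points = unname(x$points))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$points, path, sep = ",", row.names = FALSE,
                       col.names = c("x", "y"), quote = FALSE)
  }
  invisible(path)
}

#' Generate a dense circular contour
#'
#' Utility used for analytic ground truth and snake initialization.
#'
#' @param center `(x, y)` center in pixel coordinates.
#' @param radius radius in pixels.
#' @param n number of points (default: about one per boundary pixel).
#' @return a [contour()] whose points all lie exactly at distance `radius`
#'   from `center`, ordered counterclockwise in image coordinates.
#' @export
circle_contour <- function(center, radius, n = max(64L, ceiling(2 * pi * radius))) {
  stopifnot(radius > 0, n >= 3)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)))
}
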