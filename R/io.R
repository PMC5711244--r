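#' Read a 2D grayscale image
#'
#' Supports 8/16-bit PNG and TIFF (decoded to float intensities on a 0--255
#' scale) and plain-text CSV matrices of raw intensities (no header, one
#' image row per line). Images with color channels are converted to
#' grayscale by the channel average.
#'
#' @param path image file; format chosen by extension
#'   (`png`, `tif`/`tiff`, anything else is read as CSV).
#' @return numeric matrix (rows x cols).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    collapse_channels(a) * 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    collapse_channels(a) * 255
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

collapse_channels <- function(a) {
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    keep <- min(nch, 3L)           # drop alpha
    apply(a[, , seq_len(keep), drop = FALSE], c(1, 2), mean)
  } else a
}

#' Write a grayscale image as PNG
#'
#' Intensities are clipped to `[0, 255]` and written as 8-bit grayscale.
#'
#' @param image numeric matrix on a 0--255 scale.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}
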