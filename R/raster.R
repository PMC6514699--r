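#' Raster image container
#'
#' A `raster_image` is a numeric array of 8-bit intensities in `[0, 255]`,
#' stored width-major like [EBImage::Image]: the first array dimension is x
#' (increasing rightward), the second is y (increasing downward).  RGB images
#' carry a third dimension of extent 3.  All coordinates used throughout the
#' package are 0-based pixel-center coordinates with the origin at the
#' top-left pixel, so pixel `(x, y)` lives at array index `[x + 1, y + 1]`.
#'
#' @param px Numeric matrix (grayscale) or width x height x 3 array (RGB)
#'   with values in `[0, 255]`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(px) {
  if (!is.numeric(px) || is.null(dim(px)))
    stop_invalid_input("pixel data must be a numeric matrix or array")
  nd <- length(dim(px))
  if (!(nd == 2L || (nd == 3L && dim(px)[3] == 3L)))
    stop_invalid_input("pixel data must be width x height or width x height x 3")
  if (dim(px)[1] < 1L || dim(px)[2] < 1L)
    stop_invalid_input("image must be at least 1 x 1 pixel")
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop_invalid_input("intensities must be finite and within [0, 255]")
  structure(px, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("<raster_image> %d x %d px, %s, intensity range [%.1f, %.1f]\n",
              d[1], d[2], kind, min(x), max(x)))
  invisible(x)
}

img_width    <- function(img) dim(img)[1]
img_height   <- function(img) dim(img)[2]
img_is_rgb   <- function(img) length(dim(img)) == 3L
img_channel  <- function(img, i) {
  if (img_is_rgb(img)) unclass(img)[, , i] else unclass(img)
}

#' Read a PNG or JPEG image
#'
#' Reads an 8-bit PNG or JPEG file into a [raster_image].  Alpha channels are
#' dropped; single-channel files come back as grayscale matrices.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A [raster_image].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop_invalid_input(sprintf("file not found: %s", path))
  x <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(x)
  if (length(d) == 3L && d[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(d) == 3L && d[3] == 2L) x <- x[, , 1]  # gray + alpha
  raster_image(round(x * 255))
}

#' Write a raster image to PNG
#'
#' @param img A [raster_image].
#' @param path Output path; the extension selects the format (png/jpeg/tiff).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  cm <- if (img_is_rgb(img)) EBImage::Color else EBImage::Grayscale
  EBImage::writeImage(EBImage::Image(unclass(img) / 255, colormode = cm), path)
  invisible(path)
}

#' Binary mask container
#'
#' A `binary_mask` is an integer matrix of exactly 0 (background) and 1
#' (foreground), stored in the same width-major layout as [raster_image].
#' Foreground follows the dark-object polarity: leaf, frame and tick pixels
#' are 1 on the light plate background.
#'
#' @param m Matrix of 0/1 values.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(m) {
  if (!is.matrix(m)) stop_invalid_input("mask must be a matrix")
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop_invalid_input("mask values must be exactly 0 or 1")
  storage.mode(m) <- "integer"
  structure(m, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground pixels (%.1f%%)\n",
              dim(x)[1], dim(x)[2], sum(x), 100 * mean(x)))
  invisible(x)
}

# Plain numeric matrix view of a mask/image without the class attribute.
as_matrix <- function(x) {
  x <- unclass(x)
  storage.mode(x) <- "double"
  x
}

# Clamp intensities to [0, 255], preserving dim attributes.
clamp255 <- function(x) pmax(pmin(x, 255), 0)
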