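#' Pre-processing configuration
#'
#' Parameters for the grayscale / smoothing / binarization front end.
#' The grayscale conversion is a weighted average of the R, G and B channels;
#' the default weights are the ITU-R BT.601 luma coefficients.  `gauss_sigma`
#' is the standard deviation (pixels) of the Gaussian smoothing kernel;
#' `sigma = 0` disables smoothing entirely.
#'
#' @param gray_weights Non-negative weights for (R, G, B); must sum to 1
#'   within 1e-9.
#' @param gauss_sigma Gaussian smoothing standard deviation in pixels, >= 0.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold in `[0, 255]`, used only when
#'   `threshold_method = "fixed"`.  Pixels `<=` the threshold become
#'   foreground.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(gray_weights = c(0.299, 0.587, 0.114),
                              gauss_sigma = 1,
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = 128) {
  threshold_method <- match.arg(threshold_method)
  if (length(gray_weights) != 3L || any(!is.finite(gray_weights)) ||
      any(gray_weights < 0))
    stop_invalid_param("gray_weights must be three non-negative numbers")
  if (abs(sum(gray_weights) - 1) > 1e-9)
    stop_invalid_param("gray_weights must sum to 1 (within 1e-9)")
  if (!is.finite(gauss_sigma) || gauss_sigma < 0)
    stop_invalid_param("gauss_sigma must be >= 0")
  if (!is.finite(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255)
    stop_invalid_param("fixed_threshold must be in [0, 255]")
  structure(list(gray_weights = as.numeric(gray_weights),
                 gauss_sigma = gauss_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "preprocess_config")
}

#' Convert an RGB image to grayscale by weighted averaging
#'
#' Each output pixel is `round(wR*R + wG*G + wB*B)`.
#'
#' @param image An RGB [raster_image].
#' @param config A [preprocess_config] supplying the channel weights.
#' @return A grayscale [raster_image] of the same dimensions.
#' @export
to_grayscale <- function(image, config = preprocess_config()) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  if (!img_is_rgb(image))
    stop_invalid_input("to_grayscale() requires an RGB image")
  w <- config$gray_weights
  g <- w[1] * img_channel(image, 1) + w[2] * img_channel(image, 2) +
    w[3] * img_channel(image, 3)
  raster_image(round(g))
}

# Symmetric (mirror-with-edge) boundary index for positions 1-r .. n+r.
reflect_index <- function(n, r) {
  i <- seq.int(1L - r, n + r)
  k <- (i - 1L) %% (2L * n)
  k <- ifelse(k < 0L, k + 2L * n, k)
  ifelse(k < n, k + 1L, 2L * n - k)
}

gaussian_kernel_1d <- function(sigma, radius) {
  w <- exp(-(seq.int(-radius, radius))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing with reflective borders
#'
#' Convolves a grayscale image with a normalized, truncated 2D Gaussian
#' (radius `ceiling(4 * sigma)`).  Borders are handled by mirror reflection,
#' which conserves the image mean exactly.  `sigma = 0` returns the input
#' unchanged.
#'
#' @param image A grayscale [raster_image].
#' @param sigma Standard deviation in pixels, >= 0.
#' @return A grayscale [raster_image]; values are continuous (not re-rounded).
#' @export
smooth <- function(image, sigma) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  if (img_is_rgb(image))
    stop_invalid_input("smooth() requires a grayscale image")
  if (!is.finite(sigma) || sigma < 0)
    stop_invalid_param("sigma must be >= 0")
  if (sigma == 0) return(image)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- gaussian_kernel_1d(sigma, r)
  m <- as_matrix(image)
  pad <- m[reflect_index(nrow(m), r), reflect_index(ncol(m), r), drop = FALSE]
  f <- EBImage::filter2(EBImage::Image(pad), outer(k1, k1))
  out <- EBImage::imageData(f)[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)),
                               drop = FALSE]
  # FFT round-off can nudge values a hair outside [0, 255]
  raster_image(clamp255(out))
}

#' Otsu threshold of an 8-bit grayscale image
#'
#' Returns the integer threshold `t` in `0..254` that maximizes the
#' between-class variance of the split `{0..t} | {t+1..255}`; ties are broken
#' toward the smallest `t`.  With the package's dark-foreground polarity,
#' pixels `<= t` are foreground.
#'
#' @param v Numeric vector/matrix of intensities in `[0, 255]` (rounded to
#'   integers internally).
#' @return Integer threshold in `0..254`.
#' @export
otsu_threshold <- function(v) {
  v <- as.integer(round(as.numeric(v)))
  if (length(unique(v)) < 2L)
    stop_degenerate_image("constant image: Otsu threshold undefined (no two classes)")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu  <- cumsum(p * levels)
  muT <- mu[256]
  mu0 <- mu[1:255]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (muT * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  which.max(sigma_b) - 1L  # first maximum -> smallest t
}

#' Binarize a grayscale image (dark foreground)
#'
#' Maps dark objects (leaf, frame, tick marks) to 1 and the light plate
#' background to 0.  The threshold is chosen by Otsu's criterion on the
#' rounded 8-bit histogram unless a fixed threshold is configured.
#'
#' @param image A grayscale [raster_image].
#' @param config A [preprocess_config].
#' @return A [binary_mask] with attribute `"threshold"`.
#' @export
binarize <- function(image, config = preprocess_config()) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  if (img_is_rgb(image))
    stop_invalid_input("binarize() requires a grayscale image")
  v <- round(as_matrix(image))
  thr <- if (config$threshold_method == "otsu") otsu_threshold(v)
         else config$fixed_threshold
  m <- binary_mask((v <= thr) * 1L)
  attr(m, "threshold") <- thr
  m
}

#' Full pre-processing front end
#'
#' Grayscale conversion (if needed), Gaussian smoothing and binarization in
#' one call.
#'
#' @param image A [raster_image] (RGB or grayscale).
#' @param config A [preprocess_config].
#' @return A [binary_mask] with attributes `"threshold"` and `"gray"` (the
#'   smoothed grayscale image).
#' @export
preprocess <- function(image, config = preprocess_config()) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  g <- if (img_is_rgb(image)) to_grayscale(image, config) else image
  g <- smooth(g, config$gauss_sigma)
  m <- binarize(g, config)
  attr(m, "gray") <- g
  m
}
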