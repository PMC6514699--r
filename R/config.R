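#' Run configuration
#'
#' Nested configuration for the measurement pipeline.  Defaults describe the
#' synthetic bench plate: a 120 x 90 mm black frame, 3 mm thick, with 1-mm
#' ticks 3 mm long on its upper and left borders, rectified at 10 px/mm with
#' a 5 mm margin.
#'
#' @param plate List: `width_mm`, `height_mm` (outer frame dimensions),
#'   `frame_thickness_mm`, `tick_spacing_mm`, `tick_len_mm`, `px_per_mm`
#'   (rectified resolution), `margin_mm` (rectified margin).
#' @param preprocess List passed to [preprocess_config].
#' @param calibration List: `method` is `"contour"` or `"hough"`.
#' @param ticks List: `kernel_base` and `kernel_ref_width` for
#'   [tick_kernel_len], `tie_tol_px` for tick/edge coincidence.
#' @param seed Integer seed recorded in reports.
#' @return A `leafrect_config` object.
#' @export
leafrect_config <- function(plate = list(), preprocess = list(),
                            calibration = list(), ticks = list(), seed = 0L) {
  cfg <- list(
    plate = utils::modifyList(list(width_mm = 120, height_mm = 90,
                                   frame_thickness_mm = 3, tick_spacing_mm = 1,
                                   tick_len_mm = 3, px_per_mm = 10,
                                   margin_mm = 5), plate),
    preprocess = utils::modifyList(list(gray_weights = c(0.299, 0.587, 0.114),
                                        gauss_sigma = 1,
                                        threshold_method = "otsu",
                                        fixed_threshold = 128), preprocess),
    calibration = utils::modifyList(list(method = "contour"), calibration),
    ticks = utils::modifyList(list(kernel_base = 49, kernel_ref_width = 3264,
                                   tie_tol_px = 0.5), ticks),
    seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "leafrect_config")
}

validate_config <- function(cfg) {
  p <- cfg$plate
  num_pos <- c(p$width_mm, p$height_mm, p$frame_thickness_mm,
               p$tick_spacing_mm, p$tick_len_mm, p$px_per_mm)
  if (any(!is.finite(num_pos)) || any(num_pos <= 0) || p$margin_mm < 0)
    stop_invalid_param("plate geometry values must be positive")
  do.call(preprocess_config, cfg$preprocess)  # validates
  if (!cfg$calibration$method %in% c("contour", "hough"))
    stop_invalid_param("calibration method must be 'contour' or 'hough'")
  if (cfg$ticks$kernel_base < 1 || cfg$ticks$kernel_ref_width < 1)
    stop_invalid_param("tick kernel calibration must be positive")
  invisible(cfg)
}

#' Load a configuration from YAML
#'
#' Reads a YAML file and merges it (recursively) over the package defaults.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A [leafrect_config].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(leafrect_config())
  if (!file.exists(path)) stop_usage(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  leafrect_config(plate = y$plate %||% list(),
                  preprocess = y$preprocess %||% list(),
                  calibration = y$calibration %||% list(),
                  ticks = y$ticks %||% list(),
                  seed = y$seed %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap order-sensitive checksum of the serialized configuration, recorded in
# report headers for reproducibility.
config_checksum <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  b <- utf8ToInt(s)
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% .Machine$integer.max)
}
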