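#' Traced object contour
#'
#' Boundary trace of a connected foreground component, with the pixel counts
#' needed by the area/perimeter ratios: `pixel_count_interior` is the number
#' of pixels enclosed by the outermost contour (boundary included, interior
#' holes filled), `pixel_count_boundary` the number of distinct boundary
#' pixels on the 8-connected trace.
#'
#' @param points N x 2 matrix of 0-based (x, y) boundary pixels in trace order.
#' @param pixel_count_interior Pixels enclosed by the outer contour.
#' @param pixel_count_boundary Distinct boundary pixels.
#' @param filled Optional logical matrix of the filled component (kept for
#'   downstream pixel counting).
#' @return A `leaf_contour` object.
#' @export
lf_contour <- function(points, pixel_count_interior, pixel_count_boundary,
                       filled = NULL) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 1L) stop_invalid_input("contour has no points")
  if (pixel_count_interior < pixel_count_boundary)
    stop_invalid_input("interior pixel count cannot be below the boundary count")
  structure(list(points = points,
                 pixel_count_interior = as.integer(pixel_count_interior),
                 pixel_count_boundary = as.integer(pixel_count_boundary),
                 filled = filled),
            class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour> %d boundary px, %d interior px, bbox x [%d, %d] y [%d, %d]\n",
              x$pixel_count_boundary, x$pixel_count_interior,
              min(x$points[, 1]), max(x$points[, 1]),
              min(x$points[, 2]), max(x$points[, 2])))
  invisible(x)
}

# Build a leaf_contour from a logical component matrix.  The outer contour is
# traced on the hole-filled component, so lesions/wormholes inside the object
# do not affect the counts.
contour_from_component <- function(comp) {
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  oc <- EBImage::ocontour(EBImage::Image(filled * 1))[[1]]
  lf_contour(points = oc,
             pixel_count_interior = sum(filled),
             pixel_count_boundary = nrow(unique(oc)),
             filled = filled)
}

#' Extract the leaf and frame contours from a calibrated mask
#'
#' Labels the connected foreground components and keeps the two dominant
#' ones: the largest (by enclosed area) is the black rectangular frame, the
#' second largest the leaf.  Tick marks and noise blobs rank far below and
#' are ignored.  Component ranking uses enclosed (filled) area rather than
#' boundary length so that strongly serrated leaves cannot outrank the frame.
#'
#' @param mask A [binary_mask] of the rectified scene.
#' @return List with elements `leaf` and `frame`, both [lf_contour] objects.
#' @export
extract_leaf_and_frame <- function(mask) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(as_matrix(mask))))
  nlab <- max(lab)
  if (nlab < 2L)
    stop_scene_invalid(sprintf(
      "expected at least 2 connected components (frame + leaf), found %d", nlab))
  ord <- rank_components_by_enclosed_area(lab)
  frame <- contour_from_component(lab == ord[1])
  leaf  <- contour_from_component(lab == ord[2])
  fr <- bounding_rect(frame)
  lr <- bounding_rect(leaf)
  if (!(lr$x_min > fr$x_min && lr$x_max < fr$x_max &&
        lr$y_min > fr$y_min && lr$y_max < fr$y_max))
    stop_scene_invalid("leaf does not lie strictly inside the frame's outer boundary")
  list(leaf = leaf, frame = frame)
}

#' Positive circumscribed rectangle of a contour
#'
#' The axis-aligned bounding rectangle: extreme x and y coordinates of the
#' contour points.  Corner A is `(x_min, y_min)`, corner B `(x_max, y_max)`;
#' the pixel extents `Length = x_max - x_min` and `Height = y_max - y_min`
#' follow the max-minus-min convention (interior pixel counts use
#' `max - min + 1`).
#'
#' @param contour An [lf_contour], or an N x 2 matrix of points.
#' @return An `axis_rect` with fields `x_min`, `x_max`, `y_min`, `y_max` and
#'   derived `length_px`, `height_px`.
#' @export
bounding_rect <- function(contour) {
  pts <- if (inherits(contour, "leaf_contour")) contour$points else
    matrix(as.numeric(contour), ncol = 2)
  if (nrow(pts) < 1L || anyNA(pts)) stop_invalid_input("empty contour")
  r <- list(x_min = min(pts[, 1]), x_max = max(pts[, 1]),
            y_min = min(pts[, 2]), y_max = max(pts[, 2]))
  r$length_px <- r$x_max - r$x_min
  r$height_px <- r$y_max - r$y_min
  structure(r, class = "axis_rect")
}

#' @export
print.axis_rect <- function(x, ...) {
  cat(sprintf("<axis_rect> x [%g, %g], y [%g, %g]  (Length %g px, Height %g px)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$length_px, x$height_px))
  invisible(x)
}

# ---- tick-mark scale reading -----------------------------------------------

# Directional dilation kernel length: calibrated as 49 px for ~3264-px
# captures and scaled proportionally with image width (odd, minimum 3).
tick_kernel_len <- function(image_width, base = 49, ref_width = 3264) {
  k <- max(3L, as.integer(round(base * image_width / ref_width)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Most frequent value of an integer vector.
int_mode <- function(v) {
  t <- table(v)
  as.integer(names(t)[which.max(t)])
}

# Read tick centroids along one border of the frame.  `m` is the mask matrix
# oriented so the scan runs along dim 1 (tick positions) and into the plate
# along dim 2; the top ruler uses the mask as-is, the left ruler the
# transpose.  Returns centroid positions (0-based, along dim 1).
scan_ruler <- function(m, outer_lo, pos_range, klen, max_depth) {
  cols <- (pos_range[1]:pos_range[2]) + 1L
  depth <- outer_lo + seq_len(max_depth)                 # 1-based dim-2 indices
  depth <- depth[depth <= ncol(m)]
  sub <- m[cols, depth, drop = FALSE]
  # first background pixel after the frame is entered: the outer frame row is
  # only partially covered after rectification, so skip leading background
  fg1 <- max.col(sub == 1, ties.method = "first")        # first foreground step
  fg1[rowSums(sub) == 0L] <- length(depth) + 1L
  after <- col(sub) > fg1[row(sub)]
  z <- (sub == 0) & after
  first0 <- max.col(z, ties.method = "first")
  first0[rowSums(z) == 0L] <- length(depth) + 1L
  inner <- int_mode(first0)                              # frame inner edge + 1
  d <- first0 - inner
  d <- d[d > 0]
  if (length(d) < 3L)
    stop_scale_unreadable("no tick marks found beyond the frame's inner edge")
  band_depth <- max(2L, as.integer(round(stats::quantile(d, 0.9))))
  band <- depth[inner - 1L + seq_len(min(band_depth, length(depth) - inner + 1L))]
  bm <- m[cols, band, drop = FALSE]
  # rectification residuals can push the frame's inner edge a pixel into the
  # band; ruler slices are sparse (ticks cover ~tick width / pitch of the
  # border) while frame slices are nearly solid, so drop high-occupancy slices
  bm[, colMeans(bm) > 0.6] <- 0
  # reconnect broken ticks by dilating along the tick stroke direction only
  # (dim 2 of bm runs into the plate, along the stroke)
  kern <- matrix(1, nrow = 1, ncol = klen)
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image((bm > 0) * 1), kern))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(dil)))
  ids <- lab[bm > 0]
  pos <- (row(bm) - 1L)[bm > 0] + pos_range[1]           # 0-based positions
  if (length(ids) == 0L) stop_scale_unreadable("no tick pixels in the ruler band")
  sizes <- tapply(ids, ids, length)
  keep <- as.integer(names(sizes)[sizes >= 0.3 * stats::median(sizes)])
  # a tick clipped by the scan window has a biased centroid: drop components
  # touching the window boundary
  pmin_c <- tapply(pos, ids, min)
  pmax_c <- tapply(pos, ids, max)
  clipped <- as.integer(names(pmin_c)[pmin_c <= pos_range[1] |
                                        pmax_c >= pos_range[2]])
  keep <- setdiff(keep, clipped)
  if (!length(keep)) stop_scale_unreadable("no usable ticks in the ruler band")
  cent <- tapply(pos[ids %in% keep], ids[ids %in% keep], mean)
  sort(as.numeric(cent))
}

# Tick centroids must sit on a uniform lattice (the engraved millimetre
# pitch).  Thresholding can lose ticks entirely and partially washed-out or
# laterally merged ticks report displaced centroids, so the lattice is fitted
# by consensus: the pitch comes from the median adjacent spacing, the anchor
# is the position with the most lattice-consistent support, off-lattice
# centroids are discarded, same-slot fragments are averaged, and the pitch is
# re-estimated by least squares over the surviving slots.  Errors only when
# fewer than 3 consistent ticks remain.  Returns the cleaned positions with
# the pitch (px) attached as attribute "pitch_px".
snap_ticks_to_lattice <- function(p, which, max_resid = 0.25,
                                  pitch_prior = NULL) {
  if (length(p) < 3L)
    stop_scale_unreadable(sprintf(
      "fewer than 3 ticks recovered on the %s border", which))
  med <- if (!is.null(pitch_prior)) pitch_prior else stats::median(diff(p))
  if (!is.finite(med) || med <= 0)
    stop_scale_unreadable(sprintf("degenerate tick spacing on the %s border", which))
  # circular deviation of each pairwise difference from the lattice
  dev <- function(delta) {
    r <- (delta %% med + med) %% med
    pmin(r, med - r)
  }
  support <- vapply(p, function(pi) sum(dev(p - pi) <= max_resid * med), 0L)
  anchor <- p[which.max(support)]
  keep <- dev(p - anchor) <= max_resid * med
  p <- p[keep]
  if (length(p) < 3L)
    stop_scale_unreadable(sprintf(
      "fewer than 3 lattice-consistent ticks on the %s border", which))
  # collapse fragments that landed in the same lattice slot, then refine the
  # pitch by least squares over slot indices
  k <- round((p - anchor) / med)
  p <- as.numeric(tapply(p, k, mean))
  k <- sort(unique(k))
  pitch <- sum((k - mean(k)) * (p - mean(p))) / sum((k - mean(k))^2)
  if (!is.finite(pitch) || pitch <= 0 ||
      stats::median(abs(diff(p) / diff(k) - pitch)) > 0.2 * pitch)
    stop_scale_unreadable(sprintf(
      "inconsistent tick spacing on the %s border (median %.2f px)", which, med))
  # with a known rectification scale the recovered pitch must agree with it;
  # a gross mismatch means the lattice locked onto a tick-loss harmonic
  if (!is.null(pitch_prior) && abs(pitch - pitch_prior) > 0.3 * pitch_prior)
    stop_scale_unreadable(sprintf(
      "tick pitch on the %s border (%.2f px) contradicts the rectified scale (%.2f px)",
      which, pitch, pitch_prior))
  structure(p, pitch_px = pitch)
}

#' Read the physical scale from the frame's tick marks
#'
#' Locates the millimetre tick marks engraved just inside the frame's upper
#' and left borders.  Ticks broken by binarization are reconnected by
#' dilating with a directional structuring element (1 x k for the vertical
#' ticks of the top ruler, k x 1 for the horizontal ticks of the left ruler;
#' `k` scales with image width, see [tick_kernel_len]).  Each tick is reduced
#' to its centroid and the pixel-per-millimetre scale derived from the median
#' adjacent-tick spacing.
#'
#' @param mask A [binary_mask] of the rectified scene.
#' @param frame The frame [lf_contour] from [extract_leaf_and_frame].
#' @param tick_spacing_mm Physical tick pitch (default 1 mm).
#' @param kernel_base,kernel_ref_width Dilation kernel calibration (49 px at
#'   a 3264-px image width).
#' @param max_depth_px How far inside the frame border to search for ticks.
#' @param expected_pitch_px Optional prior on the tick pitch in pixels (known
#'   by construction on a rectified image: `px_per_mm * tick_spacing_mm`).
#'   When given it anchors the lattice fit and guards against locking onto a
#'   multiple of the true pitch when many ticks are lost.
#' @return A `tick_scale` with sorted `top_tick_xs`, `left_tick_ys`,
#'   `mm_per_tick`, `px_per_mm_x`, `px_per_mm_y`.
#' @export
read_tick_scale <- function(mask, frame, tick_spacing_mm = 1,
                            kernel_base = 49, kernel_ref_width = 3264,
                            max_depth_px = NULL, expected_pitch_px = NULL) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  m <- unclass(mask)
  fb <- bounding_rect(frame)
  klen <- tick_kernel_len(dim(m)[1], kernel_base, kernel_ref_width)
  if (is.null(max_depth_px))
    max_depth_px <- max(10L, as.integer(round(0.2 * min(fb$length_px, fb$height_px))))
  inset_x <- max(4L, as.integer(round(0.03 * fb$length_px)))
  inset_y <- max(4L, as.integer(round(0.03 * fb$height_px)))
  range_x <- c(fb$x_min + inset_x, fb$x_max - inset_x)
  range_y <- c(fb$y_min + inset_y, fb$y_max - inset_y)
  xs <- scan_ruler(m, outer_lo = fb$y_min, pos_range = range_x,
                   klen = klen, max_depth = max_depth_px)
  ys <- scan_ruler(t(m), outer_lo = fb$x_min, pos_range = range_y,
                   klen = klen, max_depth = max_depth_px)
  xs <- snap_ticks_to_lattice(xs, "upper", pitch_prior = expected_pitch_px)
  ys <- snap_ticks_to_lattice(ys, "left", pitch_prior = expected_pitch_px)
  structure(list(top_tick_xs = xs, left_tick_ys = ys,
                 mm_per_tick = tick_spacing_mm,
                 px_per_mm_x = attr(xs, "pitch_px") / tick_spacing_mm,
                 px_per_mm_y = attr(ys, "pitch_px") / tick_spacing_mm,
                 top_coverage = range_x, left_coverage = range_y),
            class = "tick_scale")
}

#' @export
print.tick_scale <- function(x, ...) {
  cat(sprintf("<tick_scale> %d top ticks, %d left ticks, %.3f / %.3f px per mm (x / y)\n",
              length(x$top_tick_xs), length(x$left_tick_ys),
              x$px_per_mm_x, x$px_per_mm_y))
  invisible(x)
}

# Physical span of [lo, hi] against one ruler: (n - 1) tick pitches between
# the n ticks strictly inside the span, plus the fractional end segments from
# each edge to its nearest inner tick.  An edge within tie_tol of a tick
# counts the tick and contributes a zero fraction.  The pitch count between
# the outermost inner ticks is taken on the millimetre lattice
# (round(gap / pitch)), which equals n - 1 on a complete ruler and stays
# correct when an occasional tick was lost to thresholding.
ruler_span_mm <- function(lo, hi, ticks, mm_per_tick, px_per_mm, tie_tol = 0.5,
                          coverage = NULL) {
  pitch_px <- mm_per_tick * px_per_mm
  if (is.null(coverage))
    coverage <- c(min(ticks) - 1.5 * pitch_px, max(ticks) + 1.5 * pitch_px)
  if (lo < coverage[1] || hi > coverage[2])
    stop_out_of_range("rectangle extends beyond the tick-covered span of the ruler")
  inside <- ticks[ticks > lo - tie_tol & ticks < hi + tie_tol]
  n <- length(inside)
  if (n == 0L) return((hi - lo) / px_per_mm)
  n_pitch <- round((max(inside) - min(inside)) / pitch_px)
  gap_lo <- min(inside) - lo
  gap_hi <- hi - max(inside)
  if (gap_lo <= tie_tol) gap_lo <- 0
  if (gap_hi <= tie_tol) gap_hi <- 0
  n_pitch * mm_per_tick + (gap_lo + gap_hi) / px_per_mm
}

#' Physical length and width of the bounding rectangle from the rulers
#'
#' Projects the rectangle's sides onto the tick rulers: the x-span is read
#' against the top ruler and the y-span against the left ruler.  The physical
#' length is `(n - 1)` tick pitches between the `n` ticks strictly inside the
#' span, plus the sub-tick fractions from each rectangle edge to the nearest
#' inner tick (converted with the local pixel-per-millimetre scale).
#'
#' @param rect An [bounding_rect] `axis_rect` of the leaf.
#' @param scale A `tick_scale` from [read_tick_scale].
#' @param tie_tol_px Edges within this distance of a tick centre count the
#'   tick with zero fraction (default 0.5 px).
#' @return List with `length_mm` (x extent) and `width_mm` (y extent).
#' @export
length_width_from_ticks <- function(rect, scale, tie_tol_px = 0.5) {
  list(length_mm = ruler_span_mm(rect$x_min, rect$x_max, scale$top_tick_xs,
                                 scale$mm_per_tick, scale$px_per_mm_x, tie_tol_px,
                                 coverage = scale$top_coverage),
       width_mm  = ruler_span_mm(rect$y_min, rect$y_max, scale$left_tick_ys,
                                 scale$mm_per_tick, scale$px_per_mm_y, tie_tol_px,
                                 coverage = scale$left_coverage))
}

#' Pixel counts driving the area and perimeter ratios
#'
#' `Pt` is the number of pixels enclosed by the leaf's outermost contour
#' (interior holes from lesions or wormholes are filled), `Pc` the number of
#' distinct pixels on the traced leaf boundary, `Prt` the interior pixel
#' count of the leaf's positive circumscribed rectangle
#' (`(dx + 1) * (dy + 1)`), and `Pct` its boundary pixel count
#' (`2(dx + 1) + 2(dy + 1) - 4`).
#'
#' @param leaf The leaf [lf_contour].
#' @param rect The leaf's [bounding_rect].
#' @return A `contour_stats` object with fields `Pt`, `Pc`, `Prt`, `Pct`.
#' @export
pixel_counts <- function(leaf, rect) {
  lb <- bounding_rect(leaf)
  if (lb$x_min < rect$x_min || lb$x_max > rect$x_max ||
      lb$y_min < rect$y_min || lb$y_max > rect$y_max)
    stop_invalid_input("leaf contour is not contained in the rectangle")
  dx <- rect$x_max - rect$x_min
  dy <- rect$y_max - rect$y_min
  contour_stats(Pt = leaf$pixel_count_interior,
                Pc = leaf$pixel_count_boundary,
                Prt = (dx + 1) * (dy + 1),
                Pct = 2 * (dx + 1) + 2 * (dy + 1) - 4)
}

#' @rdname pixel_counts
#' @param Pt,Pc,Prt,Pct Pixel counts (see above).
#' @export
contour_stats <- function(Pt, Pc, Prt, Pct) {
  if (any(!is.finite(c(Pt, Pc, Prt, Pct))) || any(c(Pt, Pc, Prt, Pct) <= 0))
    stop_invalid_stats("all pixel counts must be positive")
  if (Prt < Pt)
    stop_invalid_stats("rectangle interior count cannot be below the leaf count")
  structure(list(Pt = Pt, Pc = Pc, Prt = Prt, Pct = Pct),
            class = "contour_stats")
}

#' Leaf area and perimeter from pixel-count ratios
#'
#' With the positive circumscribed rectangle as the dynamic reference object:
#' `Sr = Lr * Wr`, `S = Sr * Pt / Prt`, `Cr = 2 (Lr + Wr)`,
#' `C = Cr * Pc / Pct`.  Inputs are in millimetres; the area is returned in
#' cm^2 and the perimeter in cm.
#'
#' @param stats A [contour_stats].
#' @param Lr,Wr Physical length and width of the rectangle in mm.
#' @return List with `area_cm2`, `perimeter_cm`, `rect_area_cm2`,
#'   `rect_perimeter_cm`.
#' @export
area_perimeter <- function(stats, Lr, Wr) {
  if (!inherits(stats, "contour_stats")) stop_invalid_stats("expected contour_stats")
  if (!all(is.finite(c(Lr, Wr))) || Lr <= 0 || Wr <= 0)
    stop_invalid_param("rectangle length and width must be positive")
  if (stats$Prt <= 0 || stats$Pct <= 0)
    stop_invalid_stats("zero reference pixel counts")
  Sr <- Lr * Wr                      # mm^2
  Cr <- 2 * (Lr + Wr)                # mm
  list(area_cm2 = Sr * stats$Pt / stats$Prt / 100,
       perimeter_cm = Cr * stats$Pc / stats$Pct / 10,
       rect_area_cm2 = Sr / 100,
       rect_perimeter_cm = Cr / 10)
}

#' Measure a leaf scene end to end
#'
#' Runs the full pipeline on a plate photograph: pre-processing, plate corner
#' detection, homography rectification, leaf/frame contour extraction,
#' tick-scale reading and the bounding-rectangle area/perimeter ratios.
#'
#' @param image A [raster_image] (RGB or grayscale) or a file path.
#' @param config A [leafrect_config] describing the plate geometry and
#'   processing options.
#' @return A `leaf_measurement`: `length_mm`, `width_mm`, `area_cm2`,
#'   `perimeter_cm`, `rect_area_cm2`, `rect_perimeter_cm`, the
#'   [contour_stats] in `stats`, and a `diagnostics` list (detected corners,
#'   rectification residual, tick counts, thresholds).
#' @export
measure <- function(image, config = leafrect_config()) {
  if (is.character(image)) image <- read_raster(image)
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  pcfg <- do.call(preprocess_config, config$preprocess)
  mask_raw <- with_stage("preprocess", preprocess(image, pcfg))
  quad <- with_stage("plate-detect",
                     detect_plate_quad(mask_raw, method = config$calibration$method))
  vp <- virtual_plate(config$plate$width_mm, config$plate$height_mm,
                      config$plate$px_per_mm, config$plate$margin_mm)
  H <- with_stage("homography", estimate_homography(quad, vp))
  gray <- attr(mask_raw, "gray")
  rect_img <- with_stage("rectify", rectify(gray, H, vp))
  mask <- with_stage("binarize-rectified", binarize(rect_img, pcfg))
  comp <- with_stage("contours", extract_leaf_and_frame(mask))
  rect <- bounding_rect(comp$leaf)
  scale <- with_stage("tick-scale",
                      read_tick_scale(mask, comp$frame,
                                      tick_spacing_mm = config$plate$tick_spacing_mm,
                                      kernel_base = config$ticks$kernel_base,
                                      kernel_ref_width = config$ticks$kernel_ref_width,
                                      expected_pitch_px = config$plate$px_per_mm *
                                        config$plate$tick_spacing_mm))
  lw <- with_stage("length-width",
                   length_width_from_ticks(rect, scale, config$ticks$tie_tol_px))
  stats <- with_stage("pixel-counts", pixel_counts(comp$leaf, rect))
  ap <- with_stage("area-perimeter", area_perimeter(stats, lw$length_mm, lw$width_mm))
  reproj <- max(sqrt(rowSums((apply_homography(H, quad$corners) - vp$corners)^2)))
  structure(list(length_mm = lw$length_mm,
                 width_mm = lw$width_mm,
                 area_cm2 = ap$area_cm2,
                 perimeter_cm = ap$perimeter_cm,
                 rect_area_cm2 = ap$rect_area_cm2,
                 rect_perimeter_cm = ap$rect_perimeter_cm,
                 stats = stats,
                 diagnostics = list(
                   corners_px = quad$corners,
                   corner_reproj_px = reproj,
                   homography = H,
                   n_ticks_top = length(scale$top_tick_xs),
                   n_ticks_left = length(scale$left_tick_ys),
                   px_per_mm_x = scale$px_per_mm_x,
                   px_per_mm_y = scale$px_per_mm_y,
                   threshold_raw = attr(mask_raw, "threshold"),
                   threshold_rectified = attr(mask, "threshold"))),
            class = "leaf_measurement")
}

#' @export
print.leaf_measurement <- function(x, ...) {
  cat("<leaf_measurement>\n")
  cat(sprintf("  length     %8.2f mm\n", x$length_mm))
  cat(sprintf("  width      %8.2f mm\n", x$width_mm))
  cat(sprintf("  area       %8.2f cm^2  (rectangle %.2f cm^2)\n",
              x$area_cm2, x$rect_area_cm2))
  cat(sprintf("  perimeter  %8.2f cm    (rectangle %.2f cm)\n",
              x$perimeter_cm, x$rect_perimeter_cm))
  cat(sprintf("  pixel counts: Pt %d, Prt %d, Pc %d, Pct %d\n",
              x$stats$Pt, x$stats$Prt, x$stats$Pc, x$stats$Pct))
  invisible(x)
}
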