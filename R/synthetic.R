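#' Synthetic scene specification
#'
#' Describes one ground-truthed bench scene: a light calibration plate
#' carrying a black rectangular frame with millimetre tick marks on its upper
#' and left borders, and a dark test silhouette (regular shape or leaf
#' template) lying inside the frame, imaged by a pinhole camera at a
#' configurable distance and tilt.  Degradations (Gaussian blur, additive
#' sensor noise, a dark band along the silhouette edge emulating leaf-edge
#' shadow) are optional and off by default.
#'
#' Plate coordinates are millimetres with the origin at the frame's outer
#' top-left corner, x rightward and y downward.  The camera tilts about the
#' horizontal line through the plate centre; distance controls magnification
#' through a fixed focal length calibrated so that a frontal view at 240 mm
#' fills `fill_frac` of the image width.
#'
#' @param shape One of `"square"`, `"rectangle"`, `"circle"`, `"triangle"`,
#'   `"leaf"`.
#' @param side_mm Square side (default 50).
#' @param length_mm,width_mm Rectangle dimensions (default 60 x 40).
#' @param diameter_mm Circle diameter (default 60).
#' @param base_mm,height_mm Isosceles triangle base and height (default 60).
#' @param leaf_template `"heart"`, `"oval"`, `"serrated"` or `"slender"`.
#' @param leaf_area_cm2 Target leaf silhouette area (default 25).
#' @param serration_rel Relative serration depth for the serrated template.
#' @param n_serrations Number of serration teeth.
#' @param wobble Relative amplitude of the seeded low-order boundary
#'   perturbation that individualizes leaf silhouettes.
#' @param plate_width_mm,plate_height_mm Outer frame dimensions.
#' @param frame_thickness_mm Frame bar thickness.
#' @param tick_spacing_mm,tick_len_mm Tick pitch and engraved length.
#' @param plate_margin_mm Light plate margin visible beyond the frame.
#' @param camera_distance_mm Camera-to-plate distance (230-260 typical).
#' @param tilt_deg Camera tilt in degrees, `[0, 60)`.
#' @param image_width_px Rendered image width (default 1600).
#' @param blur_sigma_px Gaussian blur applied to the rendered image.
#' @param noise_sd Additive Gaussian sensor noise (8-bit intensity units).
#' @param edge_shadow_px Width of the dark edge-shadow band around the
#'   silhouette (0 disables it).
#' @param seed RNG seed controlling noise and leaf-shape perturbations.
#' @param supersample Per-axis sub-pixel sampling factor; the default 2 takes
#'   2 x 2 = 4 supersamples per output pixel before box downsampling.
#' @param scene_res_mm Resolution of the internal plate-space raster.
#' @param interp `"bilinear"` (default) or `"nearest"` scene sampling.
#' @param fill_frac Fraction of the image width the frontal plate fills at
#'   the 240 mm reference distance.
#' @param clearance_mm Minimum gap between the silhouette and the tick marks.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(shape = c("square", "rectangle", "circle", "triangle", "leaf"),
                       side_mm = 50, length_mm = 60, width_mm = 40,
                       diameter_mm = 60, base_mm = 60, height_mm = 60,
                       leaf_template = c("heart", "oval", "serrated", "slender"),
                       leaf_area_cm2 = 25, serration_rel = 0.06,
                       n_serrations = 36, wobble = 0.04,
                       plate_width_mm = 120, plate_height_mm = 90,
                       frame_thickness_mm = 3, tick_spacing_mm = 1,
                       tick_len_mm = 3, plate_margin_mm = 10,
                       camera_distance_mm = 240, tilt_deg = 0,
                       image_width_px = 1600, blur_sigma_px = 0,
                       noise_sd = 0, edge_shadow_px = 0, seed = 0,
                       supersample = 2, scene_res_mm = 0.05,
                       interp = c("bilinear", "nearest"), fill_frac = 0.85,
                       clearance_mm = 2) {
  shape <- match.arg(shape)
  leaf_template <- match.arg(leaf_template)
  interp <- match.arg(interp)
  spec <- list(shape = shape, side_mm = side_mm, length_mm = length_mm,
               width_mm = width_mm, diameter_mm = diameter_mm,
               base_mm = base_mm, height_mm = height_mm,
               leaf_template = leaf_template, leaf_area_cm2 = leaf_area_cm2,
               serration_rel = serration_rel, n_serrations = n_serrations,
               wobble = wobble, plate_width_mm = plate_width_mm,
               plate_height_mm = plate_height_mm,
               frame_thickness_mm = frame_thickness_mm,
               tick_spacing_mm = tick_spacing_mm, tick_len_mm = tick_len_mm,
               plate_margin_mm = plate_margin_mm,
               camera_distance_mm = camera_distance_mm, tilt_deg = tilt_deg,
               image_width_px = as.integer(image_width_px),
               blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
               edge_shadow_px = edge_shadow_px, seed = as.integer(seed),
               supersample = as.integer(supersample),
               scene_res_mm = scene_res_mm, interp = interp,
               fill_frac = fill_frac, clearance_mm = clearance_mm)
  pos <- c(spec$plate_width_mm, spec$plate_height_mm, spec$frame_thickness_mm,
           spec$tick_spacing_mm, spec$tick_len_mm, spec$camera_distance_mm,
           spec$image_width_px, spec$scene_res_mm, spec$fill_frac,
           spec$supersample)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop_invalid_spec("plate, camera and rendering dimensions must be positive")
  if (!is.finite(spec$tilt_deg) || spec$tilt_deg < 0 || spec$tilt_deg >= 60)
    stop_invalid_spec("tilt_deg must lie in [0, 60)")
  if (spec$blur_sigma_px < 0 || spec$noise_sd < 0 || spec$edge_shadow_px < 0)
    stop_invalid_spec("degradation parameters must be >= 0")
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  what <- if (x$shape == "leaf") sprintf("leaf (%s, %.1f cm^2)",
                                         x$leaf_template, x$leaf_area_cm2)
          else x$shape
  cat(sprintf("<scene_spec> %s on %g x %g mm plate, %g mm / %g deg camera, %d px wide, seed %d\n",
              what, x$plate_width_mm, x$plate_height_mm,
              x$camera_distance_mm, x$tilt_deg, x$image_width_px, x$seed))
  invisible(x)
}

# ---- polygon helpers -------------------------------------------------------

#' Polygon area (shoelace) and perimeter
#'
#' @param poly N x 2 matrix of vertices (implicitly closed).
#' @return Area (absolute value) or perimeter in squared/linear input units.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' @rdname poly_area
#' @export
poly_perimeter <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

# Leaf template outlines on a unit scale, centred at the origin.
# Polar templates are sampled at n angles; the slender template is built from
# a tapered lens profile.  `wobble` adds a seeded low-order radial
# perturbation so that different seeds give individual leaves.
leaf_outline <- function(template, n = 16384, serration_rel = 0.06,
                         n_serrations = 36, wobble = 0.04) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pert <- function(ang) {
    out <- rep(1, length(ang))
    for (k in 2:6) {
      out <- out + stats::rnorm(1, 0, wobble) / k * cos(k * ang + stats::runif(1, 0, 2 * pi))
    }
    out
  }
  if (template == "heart") {
    r <- (1 - sin(phi)) * pert(phi)
    cbind(r * cos(phi), -r * sin(phi))
  } else if (template == "oval") {
    a <- 1.3; b <- 1 / 1.3
    r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2) * pert(phi)
    cbind(r * cos(phi), r * sin(phi))
  } else if (template == "serrated") {
    a <- 1.15; b <- 1 / 1.15
    r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    teeth <- 1 - serration_rel * (0.5 + 0.5 * sin(n_serrations * phi +
                                                  stats::runif(1, 0, 2 * pi)))
    r <- r * teeth * pert(phi)
    cbind(r * cos(phi), r * sin(phi))
  } else {  # slender
    a <- 4; b <- 0.5
    th <- seq(0, pi, length.out = n %/% 2 + 1)
    xs <- a * cos(th)
    half <- b * (1 - (xs / a)^2)^0.8
    hw_top <- half * pert(xs / a * pi)
    hw_bot <- half * pert(xs / a * pi + 1)
    top <- cbind(xs, -hw_top)
    bot <- cbind(rev(xs), rev(hw_bot))
    rbind(top, bot[-c(1, nrow(bot)), , drop = FALSE])
  }
}

# Usable interior of the frame: inside the frame bars, clear of the tick
# rows engraved along the upper and left borders.
usable_region <- function(spec) {
  t <- spec$frame_thickness_mm; tl <- spec$tick_len_mm; cl <- spec$clearance_mm
  list(x_min = t + tl + cl, x_max = spec$plate_width_mm - t - cl,
       y_min = t + tl + cl, y_max = spec$plate_height_mm - t - cl)
}

#' Ground-truthed silhouette polygon for a scene
#'
#' Regular shapes are exact polygons (the circle a 16384-gon); leaf templates
#' are smooth closed curves individualized by a seeded low-order boundary
#' perturbation and scaled to the requested area.  The silhouette is centred
#' in the tick-free interior of the frame.  True area and perimeter are
#' analytic for the regular shapes and computed from the dense (>= 10^4
#' vertex) polygon for leaves.
#'
#' @param spec A [scene_spec].
#' @return List: `poly` (N x 2 mm polygon in plate coordinates),
#'   `true_length_mm` (x extent), `true_width_mm` (y extent),
#'   `true_area_cm2`, `true_perimeter_cm`.
#' @export
make_silhouette <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_invalid_spec("expected a scene_spec")
  u <- usable_region(spec)
  ctr <- c((u$x_min + u$x_max) / 2, (u$y_min + u$y_max) / 2)
  n <- 16384L
  if (spec$shape == "square") {
    s <- spec$side_mm / 2
    poly <- cbind(c(-s, s, s, -s), c(-s, -s, s, s))
    truth <- list(area = spec$side_mm^2, per = 4 * spec$side_mm,
                  len = spec$side_mm, wid = spec$side_mm)
  } else if (spec$shape == "rectangle") {
    a <- spec$length_mm / 2; b <- spec$width_mm / 2
    poly <- cbind(c(-a, a, a, -a), c(-b, -b, b, b))
    truth <- list(area = spec$length_mm * spec$width_mm,
                  per = 2 * (spec$length_mm + spec$width_mm),
                  len = spec$length_mm, wid = spec$width_mm)
  } else if (spec$shape == "circle") {
    r <- spec$diameter_mm / 2
    phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    poly <- cbind(r * cos(phi), r * sin(phi))
    truth <- list(area = pi * r^2, per = pi * spec$diameter_mm,
                  len = spec$diameter_mm, wid = spec$diameter_mm)
  } else if (spec$shape == "triangle") {
    b <- spec$base_mm / 2; h <- spec$height_mm
    poly <- cbind(c(-b, b, 0), c(h / 2, h / 2, -h / 2))
    side <- sqrt(b^2 + h^2)
    truth <- list(area = spec$base_mm * h / 2, per = spec$base_mm + 2 * side,
                  len = spec$base_mm, wid = h)
  } else {
    poly <- local_seed(spec$seed,
                       leaf_outline(spec$leaf_template, n,
                                    spec$serration_rel, spec$n_serrations,
                                    spec$wobble))
    s <- sqrt(spec$leaf_area_cm2 * 100 / poly_area(poly))
    poly <- poly * s
    truth <- list(area = poly_area(poly), per = poly_perimeter(poly))
  }
  # centre the polygon's bounding box in the usable region
  bb <- c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
  poly[, 1] <- poly[, 1] - (bb[1] + bb[2]) / 2 + ctr[1]
  poly[, 2] <- poly[, 2] - (bb[3] + bb[4]) / 2 + ctr[2]
  if (is.null(truth$len)) {
    truth$len <- bb[2] - bb[1]
    truth$wid <- bb[4] - bb[3]
  }
  if (truth$len > u$x_max - u$x_min || truth$wid > u$y_max - u$y_min)
    stop_invalid_spec(sprintf(
      "silhouette (%.1f x %.1f mm) does not fit the frame interior clear of the ticks (%.1f x %.1f mm)",
      truth$len, truth$wid, u$x_max - u$x_min, u$y_max - u$y_min))
  list(poly = poly,
       true_length_mm = truth$len, true_width_mm = truth$wid,
       true_area_cm2 = truth$area / 100,
       true_perimeter_cm = truth$per / 10)
}

# Even-odd scanline fill of a polygon onto the plate-space raster
# ([nx, ny] cells of size res_mm, cell (i, j) centred at
# (x0 + (i - 0.5) res, y0 + (j - 0.5) res)).
rasterize_polygon <- function(poly, x0, y0, res, nx, ny) {
  ex <- (poly[, 1] - x0) / res + 0.5   # cell-centre coordinates
  ey <- (poly[, 2] - y0) / res + 0.5
  ex2 <- c(ex[-1], ex[1]); ey2 <- c(ey[-1], ey[1])
  dy <- ey2 - ey
  sel <- dy != 0
  kmin <- ceiling(pmin(ey, ey2))
  kmax <- ceiling(pmax(ey, ey2)) - 1
  cnt <- as.integer(pmax(0L, as.integer(kmax - kmin + 1)) * sel)
  eidx <- rep.int(seq_along(ex), cnt)
  ks <- rep.int(kmin, cnt) + sequence(cnt) - 1
  tpar <- (ks - ey[eidx]) / dy[eidx]
  xc <- ex[eidx] + tpar * (ex2[eidx] - ex[eidx])
  keep <- ks >= 1 & ks <= ny
  ks <- ks[keep]; xc <- xc[keep]
  if (length(ks) == 0L) return(matrix(FALSE, nx, ny))
  o <- order(ks, xc)
  ks <- ks[o]; xc <- xc[o]
  rk <- sequence(rle(ks)$lengths)
  a <- xc[rk %% 2L == 1L]; b <- xc[rk %% 2L == 0L]
  rows <- ks[rk %% 2L == 1L]
  cs <- pmax(1L, as.integer(ceiling(a)))
  ce <- pmin(as.integer(nx), as.integer(floor(b)))
  ok <- cs <= ce
  cs <- cs[ok]; ce <- ce[ok]; rows <- rows[ok]
  lin_s <- (rows - 1L) * (nx + 1L) + cs
  lin_e <- (rows - 1L) * (nx + 1L) + ce + 1L
  cnts <- tabulate(lin_s, nbins = ny * (nx + 1L)) -
    tabulate(lin_e, nbins = ny * (nx + 1L))
  mm <- matrix(cnts, nrow = nx + 1L, ncol = ny)
  apply(mm, 2, cumsum)[1:nx, , drop = FALSE] > 0
}

# Plate-space scene rasters: RGB channels plus the foreground indicator.
build_scene_rasters <- function(spec, sil_poly, colors) {
  res <- spec$scene_res_mm
  pm <- spec$plate_margin_mm
  W <- spec$plate_width_mm; H <- spec$plate_height_mm
  t <- spec$frame_thickness_mm
  x0 <- -pm; y0 <- -pm
  nx <- as.integer(round((W + 2 * pm) / res))
  ny <- as.integer(round((H + 2 * pm) / res))
  xs <- x0 + (seq_len(nx) - 0.5) * res
  ys <- y0 + (seq_len(ny) - 0.5) * res
  in_outer_x <- xs >= 0 & xs <= W
  in_outer_y <- ys >= 0 & ys <= H
  in_inner_x <- xs > t & xs < W - t
  in_inner_y <- ys > t & ys < H - t
  frame <- outer(in_outer_x, in_outer_y, "&") & !outer(in_inner_x, in_inner_y, "&")
  tw <- 0.3  # engraved tick width in mm
  near_mm <- function(v, sp) abs(v - round(v / sp) * sp) <= tw / 2
  ruler_x <- near_mm(xs, spec$tick_spacing_mm) & xs > t + tw & xs < W - t - tw
  ruler_y <- near_mm(ys, spec$tick_spacing_mm) & ys > t + tw & ys < H - t - tw
  band_top  <- ys >= t & ys <= t + spec$tick_len_mm
  band_left <- xs >= t & xs <= t + spec$tick_len_mm
  ticks <- outer(ruler_x, band_top, "&") | outer(band_left, ruler_y, "&")
  sil <- rasterize_polygon(sil_poly, x0, y0, res, nx, ny)
  mat <- matrix(1L, nx, ny)                      # 1 = plate
  if (spec$edge_shadow_px > 0) {
    s_nom <- spec$fill_frac * spec$image_width_px / (W + 2 * pm) *
      240 / spec$camera_distance_mm              # nominal px per mm
    r_cells <- max(1L, as.integer(round(spec$edge_shadow_px / s_nom / res)))
    brush <- EBImage::makeBrush(2L * r_cells + 1L, shape = "disc")
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(sil * 1), brush)) > 0
    mat[dil & !sil] <- 2L                        # 2 = edge shadow
  }
  mat[sil] <- 3L                                 # 3 = leaf / test shape
  mat[frame | ticks] <- 4L                       # 4 = frame and ticks
  pal <- rbind(colors$plate, colors$shadow, colors$leaf, colors$frame)
  list(channels = lapply(1:3, function(c) matrix(pal[mat, c], nx, ny)),
       indicator = matrix(as.numeric(mat >= 3L), nx, ny),
       x0 = x0, y0 = y0, res = res, nx = nx, ny = ny)
}

# Homography (3x3) mapping plate mm coordinates to image pixel coordinates
# for the given camera distance/tilt.
camera_homography <- function(spec) {
  W <- spec$plate_width_mm; H <- spec$plate_height_mm
  pm <- spec$plate_margin_mm
  wpx <- spec$image_width_px
  hpx <- as.integer(round(wpx * (H + 2 * pm) / (W + 2 * pm)))
  f <- spec$fill_frac * wpx * 240 / (W + 2 * pm)
  th <- spec$tilt_deg * pi / 180
  P <- rbind(c(f, 0, 0), c(0, f * cos(th), 0), c(0, sin(th), spec$camera_distance_mm))
  Tr <- rbind(c(1, 0, -W / 2), c(0, 1, -H / 2), c(0, 0, 1))
  A <- rbind(c(1, 0, (wpx - 1) / 2), c(0, 1, (hpx - 1) / 2), c(0, 0, 1))
  M <- A %*% P %*% Tr
  list(M = M / M[3, 3], wpx = wpx, hpx = hpx)
}

# Sample the plate-space rasters through the camera with ss x ss supersampling
# and box downsampling.  Returns one wpx x hpx matrix per input raster;
# points outside the plate raster take the per-raster background value.
project_rasters <- function(rasters, bgvals, Minv, wpx, hpx, ss, interp,
                            scn, chunk_rows = 96L) {
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  ux <- rep(seq_len(wpx) - 1, each = ss) + offs   # supersampled x positions
  out <- lapply(rasters, function(r) matrix(0, wpx, hpx))
  for (r0 in seq(1L, hpx, by = chunk_rows)) {
    r1 <- min(hpx, r0 + chunk_rows - 1L)
    nr <- r1 - r0 + 1L
    vy <- rep(seq(r0, r1) - 1, each = ss) + offs
    X <- rep(ux, times = length(vy))
    Y <- rep(vy, each = length(ux))
    den <- Minv[3, 1] * X + Minv[3, 2] * Y + Minv[3, 3]
    mx <- (Minv[1, 1] * X + Minv[1, 2] * Y + Minv[1, 3]) / den
    my <- (Minv[2, 1] * X + Minv[2, 2] * Y + Minv[2, 3]) / den
    rx <- (mx - scn$x0) / scn$res - 0.5          # 0-based raster coordinates
    ry <- (my - scn$y0) / scn$res - 0.5
    outside <- rx < -0.5 | rx > scn$nx - 0.5 | ry < -0.5 | ry > scn$ny - 0.5
    nxr <- scn$nx; nyr <- scn$ny
    if (interp == "nearest") {
      ix <- pmin(pmax(round(rx), 0), nxr - 1)
      iy <- pmin(pmax(round(ry), 0), nyr - 1)
      lin <- ix + 1 + nxr * iy
    } else {
      # shared bilinear gather indices and weights for all rasters
      rx <- pmin(pmax(rx, 0), nxr - 1)
      ry <- pmin(pmax(ry, 0), nyr - 1)
      x0i <- pmin(floor(rx), nxr - 2)
      y0i <- pmin(floor(ry), nyr - 2)
      fx <- rx - x0i; fy <- ry - y0i
      i00 <- x0i + 1 + nxr * y0i
      w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
      w01 <- (1 - fx) * fy;       w11 <- fx * fy
    }
    for (k in seq_along(rasters)) {
      r <- rasters[[k]]
      v <- if (interp == "nearest") r[lin]
           else w00 * r[i00] + w10 * r[i00 + 1] +
                w01 * r[i00 + nxr] + w11 * r[i00 + nxr + 1]
      if (any(outside)) v[outside] <- bgvals[k]
      a <- array(v, c(ss, wpx, ss, nr))
      s1 <- colSums(a)                            # (wpx, ss, nr)
      s2 <- colSums(aperm(s1, c(2, 1, 3)))        # (wpx, nr)
      out[[k]][, r0:r1] <- s2 / ss^2
    }
  }
  out
}

#' Render a synthetic calibration-plate scene
#'
#' Draws the plate, frame, tick marks and silhouette in plate space, applies
#' the projective camera implied by the scene's distance and tilt, and
#' supersamples (default 4 x 4 per pixel) for sub-pixel edge fidelity before
#' optional blur, additive noise and rounding to 8-bit.  Camera distances
#' below 235 mm add defocus blur on top of `blur_sigma_px`
#' (`0.2 px` per mm below 235), emulating close-range edge blurring.
#'
#' @param spec A [scene_spec].
#' @param with_mask If `TRUE`, also return the ground-truth foreground mask
#'   (frame, ticks and silhouette) rendered through the same camera at > 50%
#'   pixel coverage.
#' @return List with `image` (an RGB [raster_image]) and `truth`: the true
#'   silhouette length/width (mm), area (cm^2), perimeter (cm), the four
#'   frame-corner positions in image pixels (`true_corner_px`, TL TR BR BL),
#'   the applied camera [homography], the silhouette polygon, and optionally
#'   `mask`.
#' @export
render_scene <- function(spec, with_mask = FALSE) {
  if (!inherits(spec, "scene_spec")) stop_invalid_spec("expected a scene_spec")
  set.seed(spec$seed)
  sil <- make_silhouette(spec)
  colors <- list(plate = c(232, 228, 222), frame = c(25, 25, 25),
                 leaf = c(38, 72, 40), shadow = c(120, 120, 118),
                 background = c(176, 178, 183))
  scn <- build_scene_rasters(spec, sil$poly, colors)
  cam <- camera_homography(spec)
  Minv <- solve(cam$M)
  rasters <- scn$channels
  bgvals <- colors$background
  if (with_mask) {
    rasters <- c(rasters, list(scn$indicator))
    bgvals <- c(bgvals, 0)
  }
  planes <- project_rasters(rasters, bgvals, Minv, cam$wpx, cam$hpx,
                            spec$supersample, spec$interp, scn)
  sigma <- spec$blur_sigma_px + max(0, (235 - spec$camera_distance_mm) * 0.2)
  img <- array(0, c(cam$wpx, cam$hpx, 3))
  for (c in 1:3) {
    ch <- planes[[c]]
    if (sigma > 0)
      ch <- as_matrix(smooth(raster_image(clamp255(ch)), sigma))
    if (spec$noise_sd > 0)
      ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sd)
    img[, , c] <- round(clamp255(ch))
  }
  W <- spec$plate_width_mm; H <- spec$plate_height_mm
  corners_mm <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  truth <- list(true_length_mm = sil$true_length_mm,
                true_width_mm = sil$true_width_mm,
                true_area_cm2 = sil$true_area_cm2,
                true_perimeter_cm = sil$true_perimeter_cm,
                true_corner_px = apply_homography(cam$M, corners_mm),
                applied_homography = homography_from_matrix(cam$M),
                silhouette_mm = sil$poly)
  if (with_mask)
    truth$mask <- binary_mask((planes[[4]] >= 0.5) * 1L)
  list(image = raster_image(img), truth = truth)
}

#' Measurement configuration matching a scene specification
#'
#' Convenience helper: a [leafrect_config] whose plate geometry matches the
#' rendered scene, for feeding [measure] with synthetic images.
#'
#' @param spec A [scene_spec].
#' @param ... Further arguments passed to [leafrect_config].
#' @return A [leafrect_config].
#' @export
config_for_scene <- function(spec, ...) {
  leafrect_config(plate = list(width_mm = spec$plate_width_mm,
                               height_mm = spec$plate_height_mm,
                               frame_thickness_mm = spec$frame_thickness_mm,
                               tick_spacing_mm = spec$tick_spacing_mm,
                               tick_len_mm = spec$tick_len_mm),
                  ...)
}
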