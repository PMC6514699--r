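#' Detected plate corner quadrilateral
#'
#' Holds the four distortion calibration points -- the corners of the black
#' frame's outer contour -- in 0-based image pixel coordinates, canonically
#' ordered top-left, top-right, bottom-right, bottom-left.
#'
#' @param corners 4 x 2 matrix of (x, y) corner points (any order; they are
#'   re-ordered canonically).
#' @return A `plate_quad` object.
#' @export
plate_quad <- function(corners) {
  corners <- matrix(as.numeric(corners), ncol = 2)
  if (nrow(corners) != 4L || anyNA(corners))
    stop_invalid_input("plate_quad needs four finite (x, y) corners")
  if (min(stats::dist(corners)) < 1e-9)
    stop_invalid_input("plate corners must be distinct")
  corners <- order_corners(corners)
  v <- rbind(corners, corners[1, , drop = FALSE])
  cross <- sapply(1:4, function(i) {
    a <- v[i + 1, ] - v[i, ]
    b <- v[(i %% 4) + 2, ] - v[i + 1, ]
    a[1] * b[2] - a[2] * b[1]
  })
  if (any(cross <= 0))
    stop_invalid_input("plate corners do not form a convex quadrilateral")
  structure(list(corners = corners), class = "plate_quad")
}

#' @export
print.plate_quad <- function(x, ...) {
  lab <- c("TL", "TR", "BR", "BL")
  cat("<plate_quad>\n")
  for (i in 1:4)
    cat(sprintf("  %s (%8.2f, %8.2f)\n", lab[i], x$corners[i, 1], x$corners[i, 2]))
  invisible(x)
}

# Angular sort about the centroid; start at the corner closest to top-left
# (minimal x + y).  With the y-down convention ascending atan2 order is
# TL, TR, BR, BL.
order_corners <- function(corners) {
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  corners <- corners[order(ang), , drop = FALSE]
  start <- which.min(corners[, 1] + corners[, 2])
  corners[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
}

#' Virtual rectangular calibration plate
#'
#' The ideal orthogonal (frontal) projection of the plate used as the
#' rectification target.  Its four virtual calibration points are the corners
#' of the frame's outer boundary rendered at `px_per_mm`, inset by a margin
#' so the frame does not touch the rectified image border.
#'
#' @param width_mm,height_mm Physical outer dimensions of the black frame.
#' @param px_per_mm Rendering scale of the rectified image (default 10).
#' @param margin_mm Margin around the frame in the rectified image (default 5).
#' @return A `virtual_plate` with elements `corners` (4 x 2, TL TR BR BL),
#'   `out_width`, `out_height` (rectified image size in px) and the input
#'   geometry.
#' @export
virtual_plate <- function(width_mm, height_mm, px_per_mm = 10, margin_mm = 5) {
  if (!all(is.finite(c(width_mm, height_mm, px_per_mm, margin_mm))) ||
      width_mm <= 0 || height_mm <= 0 || px_per_mm <= 0 || margin_mm < 0)
    stop_invalid_param("virtual plate dimensions and scale must be positive")
  wpx <- round(width_mm * px_per_mm)
  hpx <- round(height_mm * px_per_mm)
  m <- round(margin_mm * px_per_mm)
  corners <- rbind(c(m, m),
                   c(m + wpx - 1, m),
                   c(m + wpx - 1, m + hpx - 1),
                   c(m, m + hpx - 1))
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 px_per_mm = px_per_mm, margin_mm = margin_mm,
                 corners = corners,
                 out_width = wpx + 2 * m, out_height = hpx + 2 * m),
            class = "virtual_plate")
}

# ---- contour-based corner detection ----------------------------------------

# Perpendicular distance of points to the segment p1-p2.
point_segment_dist <- function(pts, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 < 1e-12) return(sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2))
  abs((pts[, 1] - p1[1]) * d[2] - (pts[, 2] - p1[2]) * d[1]) / sqrt(len2)
}

# Douglas-Peucker on an open polyline (keeps endpoints), iterative stack form.
dp_open <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rg[1]; j <- rg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- point_segment_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > eps) {
      keep[mid[k]] <- TRUE
      stack[[length(stack) + 1]] <- c(i, mid[k])
      stack[[length(stack) + 1]] <- c(mid[k], j)
    }
  }
  which(keep)
}

# Douglas-Peucker simplification of a closed contour.  The contour is split
# at two mutually distant anchor points and each half simplified.
dp_simplify_closed <- function(pts, eps) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  a1 <- which.max((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  pts <- pts[c(a1:n, seq_len(a1 - 1)), , drop = FALSE]
  a2 <- which.max((pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2)
  # two open chains: 1..a2 and a2..n..back to 1 (closing the loop)
  k1 <- dp_open(pts[1:a2, , drop = FALSE], eps)
  chain2 <- rbind(pts[a2:n, , drop = FALSE], pts[1, , drop = FALSE])
  k2 <- dp_open(chain2, eps)
  k2 <- k2[k2 <= n - a2 + 1] + a2 - 1   # drop the duplicated closing point
  idx <- sort(unique(c(k1, k2)))
  prune_closed_polygon(pts[idx, , drop = FALSE], eps)
}

# Split points kept unconditionally by Douglas-Peucker can survive on an
# edge (notably when both anchors fall on the same side of the polygon);
# cyclically remove vertices that deviate less than eps from the chord of
# their neighbours.
prune_closed_polygon <- function(poly, eps) {
  repeat {
    nv <- nrow(poly)
    if (nv <= 3L) return(poly)
    dev <- vapply(seq_len(nv), function(i) {
      a <- poly[if (i == 1L) nv else i - 1L, ]
      b <- poly[if (i == nv) 1L else i + 1L, ]
      point_segment_dist(poly[i, , drop = FALSE], a, b)
    }, 0)
    i <- which.min(dev)
    if (dev[i] >= eps) return(poly)
    poly <- poly[-i, , drop = FALSE]
  }
}

closed_perimeter <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# Simplify a traced contour to exactly four vertices by growing the DP
# tolerance from eps_start to eps_max (fractions of the contour perimeter),
# bisecting when the vertex count jumps past 4.
simplify_to_quad <- function(pts, eps_start_frac = 0.01, growth = 1.5,
                             eps_max_frac = 0.10) {
  per <- closed_perimeter(pts)
  eps_max <- per * eps_max_frac
  schedule <- per * eps_start_frac * growth^(0:40)
  schedule <- unique(c(schedule[schedule < eps_max], eps_max))
  prev_eps <- NA_real_   # largest eps seen that still left > 4 vertices
  over_eps <- NA_real_   # smallest eps seen that left < 4 vertices
  for (eps in schedule) {
    nv <- nrow(dp_simplify_closed(pts, eps))
    if (nv == 4L) return(dp_simplify_closed(pts, eps))
    if (nv > 4L) prev_eps <- eps
    if (nv < 4L) { over_eps <- eps; break }
  }
  if (is.na(over_eps))   # still > 4 vertices at the maximum tolerance
    stop_plate_not_found(
      "could not simplify the plate contour to 4 corners within the tolerance schedule")
  # the vertex count jumped past 4: bisect for a tolerance giving exactly 4
  lo <- if (is.na(prev_eps)) per * 1e-4 else prev_eps
  hi <- over_eps
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    poly <- dp_simplify_closed(pts, mid)
    nv <- nrow(poly)
    if (nv == 4L) return(poly)
    if (nv > 4L) lo <- mid else hi <- mid
  }
  stop_plate_not_found(
    "could not simplify the plate contour to 4 corners within the tolerance schedule")
}

# Rank labelled components by the area enclosed by their outer contour
# (hole-filled), so the hollow frame ring outranks any solid leaf inside it.
# Only the `top` components by raw pixel count are filled (the rest are tick
# marks and noise specks).  Returns label ids in decreasing enclosed area.
rank_components_by_enclosed_area <- function(lab, top = 6L) {
  nlab <- max(lab)
  areas <- tabulate(as.integer(lab), nbins = nlab)
  cand <- order(areas, decreasing = TRUE)[seq_len(min(top, nlab))]
  filled <- vapply(cand, function(id)
    sum(EBImage::imageData(EBImage::fillHull(EBImage::Image((lab == id) * 1)))),
    0)
  cand[order(filled, decreasing = TRUE)]
}

# Sub-pixel corner refinement: fit a total-least-squares line to the contour
# points along each side of the quadrilateral (excluding the corner
# neighbourhoods) and intersect adjacent lines.  Douglas-Peucker vertices can
# sit tens of pixels from the true corner along an edge, so the fit is
# iterated with a shrinking capture band; each pass falls back to the
# previous corners if a side has too few supporting points.
refine_quad_corners <- function(pts, corners, bands_px = c(20, 5, 3),
                                end_frac = 0.08) {
  for (b in bands_px) {
    corners <- refine_quad_once(pts, corners, band_px = b, end_frac = end_frac)
  }
  corners
}

refine_quad_once <- function(pts, corners, band_px = 3, end_frac = 0.08) {
  lines <- vector("list", 4)
  for (i in 1:4) {
    p1 <- corners[i, ]
    p2 <- corners[(i %% 4) + 1, ]
    d <- p2 - p1
    len2 <- sum(d^2)
    if (len2 < 1e-9) return(corners)
    tp <- ((pts[, 1] - p1[1]) * d[1] + (pts[, 2] - p1[2]) * d[2]) / len2
    perp <- abs((pts[, 1] - p1[1]) * d[2] - (pts[, 2] - p1[2]) * d[1]) / sqrt(len2)
    sel <- tp > end_frac & tp < 1 - end_frac & perp < band_px
    if (sum(sel) < 10) return(corners)
    q <- pts[sel, , drop = FALSE]
    c0 <- colMeans(q)
    nvec <- svd(sweep(q, 2, c0))$v[, 2]
    rho <- sum(nvec * c0)
    # boundary-pixel centres sit ~0.5 px inside the continuous region edge;
    # move the fitted line half a pixel outward (away from the centroid)
    ctr <- colMeans(corners)
    rho <- rho + if (sum(nvec * ctr) > rho) -0.5 else 0.5
    lines[[i]] <- c(nvec, rho)                     # n . x = rho
  }
  out <- corners
  for (i in 1:4) {
    a <- lines[[if (i == 1) 4 else i - 1]]
    b <- lines[[i]]
    A <- rbind(a[1:2], b[1:2])
    if (abs(det(A)) < 1e-9) return(corners)
    out[i, ] <- solve(A, c(a[3], b[3]))
  }
  out
}

# Component enclosing the largest area and its outer contour (0-based).
largest_component_contour <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(as_matrix(mask))))
  if (max(lab) < 1L) stop_plate_not_found("mask contains no foreground component")
  id <- rank_components_by_enclosed_area(lab)[1]
  comp <- lab == id
  oc <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  list(contour = oc, component = comp, area = sum(comp))
}

#' Detect the calibration plate's four corner points
#'
#' Extracts the largest dark connected component (the black frame) from a
#' binary mask, traces its outer contour, and reduces it to a convex
#' quadrilateral.  The default reduces the contour by iterative
#' Douglas-Peucker polygon approximation; a Hough-line detector that
#' intersects the four dominant edge lines is available as an alternative.
#'
#' @param mask A [binary_mask] containing one dominant rectangular frame.
#' @param method `"contour"` (polygon approximation, default) or `"hough"`.
#' @param eps_start_frac,eps_growth,eps_max_frac Douglas-Peucker tolerance
#'   schedule, as fractions of the contour perimeter.
#' @return A [plate_quad].
#' @export
detect_plate_quad <- function(mask, method = c("contour", "hough"),
                              eps_start_frac = 0.01, eps_growth = 1.5,
                              eps_max_frac = 0.10) {
  method <- match.arg(method)
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  lc <- largest_component_contour(mask)
  if (nrow(lc$contour) < 4L)
    stop_plate_not_found("largest component is too small to be the plate frame")
  corners <- if (method == "contour") {
    coarse <- simplify_to_quad(lc$contour, eps_start_frac, eps_growth, eps_max_frac)
    refine_quad_corners(lc$contour, order_corners(coarse))
  } else {
    hough_quad(lc$contour)
  }
  tryCatch(plate_quad(corners), leafrect_invalid_input = function(e)
    stop_plate_not_found(paste("detected corners are not a convex quadrilateral:",
                               conditionMessage(e))))
}

# ---- Hough-line corner detection (optional path) ---------------------------

# Finds the four dominant lines through the frame contour points in a
# (theta, rho) accumulator, refines each by least squares on its inliers, and
# intersects opposite-orientation pairs.
hough_quad <- function(pts, theta_step_deg = 0.5, rho_step = 2) {
  thetas <- seq(0, pi - 1e-9, by = theta_step_deg * pi / 180)
  nt <- length(thetas)
  rho <- pts %*% rbind(cos(thetas), sin(thetas))
  rmax <- max(abs(rho)) + rho_step
  ri <- round(rho / rho_step)
  roff <- round(rmax / rho_step) + 1L
  nr <- 2L * roff
  lin <- (rep(seq_len(nt), each = nrow(pts)) - 1L) * nr + (as.integer(ri) + roff)
  acc <- tabulate(lin, nbins = nt * nr)
  acc <- matrix(acc, nrow = nr, ncol = nt)
  lines <- list()
  for (k in 1:4) {
    i <- arrayInd(which.max(acc), dim(acc))
    th <- thetas[i[2]]
    rh <- (i[1] - roff) * rho_step
    # refine on inliers within 2 * rho_step of the coarse line
    d <- pts[, 1] * cos(th) + pts[, 2] * sin(th) - rh
    inl <- pts[abs(d) < 2 * rho_step, , drop = FALSE]
    if (nrow(inl) >= 2) {
      # total least squares line fit through the inliers
      c0 <- colMeans(inl)
      sv <- svd(sweep(inl, 2, c0))
      nvec <- sv$v[, 2]
      th <- atan2(nvec[2], nvec[1]) %% pi
      rh <- c0[1] * cos(th) + c0[2] * sin(th)
    }
    lines[[k]] <- c(theta = th, rho = rh)
    # suppress the peak neighbourhood (with the theta ~ theta + pi wrap)
    ti <- which(pmin(abs(thetas - thetas[i[2]]),
                     pi - abs(thetas - thetas[i[2]])) < 15 * pi / 180)
    for (t in ti) {
      flip <- abs(thetas[t] - thetas[i[2]]) > pi / 2
      ctr <- if (flip) 2L * roff - i[1] else i[1]
      rr <- max(1L, ctr - 15L):min(nr, ctr + 15L)
      acc[rr, t] <- 0L
    }
  }
  th <- vapply(lines, `[[`, 0, "theta")
  grp <- abs(sin(th - th[1])) < 0.5  # parallel to line 1?
  if (sum(grp) != 2L)
    stop_plate_not_found("Hough lines do not split into two parallel pairs")
  g1 <- which(grp); g2 <- which(!grp)
  corners <- matrix(0, 4, 2)
  n <- 0L
  for (i in g1) for (j in g2) {
    A <- rbind(c(cos(lines[[i]]["theta"]), sin(lines[[i]]["theta"])),
               c(cos(lines[[j]]["theta"]), sin(lines[[j]]["theta"])))
    b <- c(lines[[i]]["rho"], lines[[j]]["rho"])
    p <- tryCatch(solve(A, b), error = function(e)
      stop_plate_not_found("Hough line intersection is degenerate"))
    n <- n + 1L
    corners[n, ] <- p
  }
  corners
}

# ---- rectification ---------------------------------------------------------

# Bilinear sampling of matrix m (0-based coordinates), edge-clamped.
bilinear_sample <- function(m, x, y) {
  w <- nrow(m); h <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  if (w == 1L) x0 <- x * 0
  if (h == 1L) y0 <- y * 0
  fx <- x - x0; fy <- y - y0
  i00 <- x0 + 1 + w * y0
  i10 <- i00 + (w > 1L)
  i01 <- i00 + w * (h > 1L)
  i11 <- i01 + (w > 1L)
  (1 - fx) * (1 - fy) * m[i00] + fx * (1 - fy) * m[i10] +
    (1 - fx) * fy * m[i01] + fx * fy * m[i11]
}

#' Rectify an image with an estimated homography
#'
#' Resamples the distorted image onto the virtual plate grid by inverse
#' mapping: every output pixel is projected back through the inverse
#' transformation matrix and sampled bilinearly from the source, so no output
#' pixel is left unfilled.
#'
#' @param image A [raster_image] (grayscale or RGB).
#' @param H A [homography] mapping image to virtual-plate coordinates.
#' @param virtual A [virtual_plate] defining the output geometry.
#' @return A [raster_image] of size `virtual$out_width x virtual$out_height`.
#' @export
rectify <- function(image, H, virtual) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  Minv <- tryCatch(solve(homography_matrix(H)), error = function(e)
    stop_singular_system("homography is not invertible"))
  wo <- virtual$out_width; ho <- virtual$out_height
  u <- rep(seq_len(wo) - 1, times = ho)
  v <- rep(seq_len(ho) - 1, each = wo)
  den <- Minv[3, 1] * u + Minv[3, 2] * v + Minv[3, 3]
  sx <- (Minv[1, 1] * u + Minv[1, 2] * v + Minv[1, 3]) / den
  sy <- (Minv[2, 1] * u + Minv[2, 2] * v + Minv[2, 3]) / den
  sample_plane <- function(m) {
    matrix(bilinear_sample(m, sx, sy), nrow = wo, ncol = ho)
  }
  out <- if (img_is_rgb(image)) {
    array(c(sample_plane(img_channel(image, 1)),
            sample_plane(img_channel(image, 2)),
            sample_plane(img_channel(image, 3))), dim = c(wo, ho, 3))
  } else {
    sample_plane(as_matrix(image))
  }
  raster_image(clamp255(out))
}
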