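test_that("frame and leaf are extracted by enclosed-area ranking", {
  mask <- toy_plate_mask()
  comp <- extract_leaf_and_frame(mask)
  fb <- bounding_rect(comp$frame)
  lb <- bounding_rect(comp$leaf)
  expect_equal(c(fb$x_min, fb$y_min, fb$x_max, fb$y_max), c(0, 0, 519, 419))
  expect_equal(c(lb$x_max - lb$x_min, lb$y_max - lb$y_min), c(80, 60))
  # the ~90 tick components rank far below the blob and are ignored
  expect_error(extract_leaf_and_frame(binary_mask(matrix(0L, 30, 30))),
               class = "leafrect_scene_invalid")
  solo <- matrix(0L, 30, 30); solo[5:25, 5:25] <- 1L
  expect_error(extract_leaf_and_frame(binary_mask(solo)),
               class = "leafrect_scene_invalid")
  # a blob outside the frame is not a valid scene
  outside <- matrix(0L, 200, 200)
  outside[50:120, 50:120] <- 1L; outside[55:115, 55:115] <- 0L  # ring
  outside[150:190, 150:190] <- 1L
  expect_error(extract_leaf_and_frame(binary_mask(outside)),
               class = "leafrect_scene_invalid")
})

test_that("bounding_rect equals the exhaustive min/max oracle", {
  # axis-aligned rectangle is its own bounding box
  m <- matrix(FALSE, 40, 40); m[6:15, 8:27] <- TRUE
  ct <- leafrect:::contour_from_component(m)
  r <- bounding_rect(ct)
  expect_equal(c(r$x_min, r$x_max, r$y_min, r$y_max), c(5, 14, 7, 26))
  expect_equal(c(r$length_px, r$height_px), c(9, 19))
  # single pixel
  r1 <- bounding_rect(matrix(c(3, 3), 1, 2))
  expect_equal(c(r1$x_min, r1$x_max, r1$length_px, r1$height_px), c(3, 3, 0, 0))
  # random clouds vs brute-force scan
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(sample(0:500, 1000, replace = TRUE), 500, 2)
    r <- bounding_rect(pts)
    expect_equal(c(r$x_min, r$x_max, r$y_min, r$y_max),
                 as.numeric(c(min(pts[, 1]), max(pts[, 1]),
                              min(pts[, 2]), max(pts[, 2]))))
  }
  expect_error(bounding_rect(matrix(numeric(0), 0, 2)),
               class = "leafrect_invalid_input")
})

test_that("tick scale reading: ideal, broken and rescaled rulers", {
  mask <- toy_plate_mask(pitch = 10)
  comp <- extract_leaf_and_frame(mask)
  sc <- read_tick_scale(mask, comp$frame)
  expect_equal(sc$px_per_mm_x, 10)
  expect_equal(sc$px_per_mm_y, 10)
  expect_true(all(abs(diff(sc$top_tick_xs) - 10) < 1e-9))
  # ticks broken by a 1 px gap reconnect to identical centroids
  broken <- toy_plate_mask(pitch = 10, broken_ticks = TRUE)
  scb <- read_tick_scale(broken, extract_leaf_and_frame(broken)$frame)
  expect_equal(scb$top_tick_xs, sc$top_tick_xs, tolerance = 1e-9)
  expect_equal(scb$left_tick_ys, sc$left_tick_ys, tolerance = 1e-9)
  # doubling the resolution doubles the scale
  big <- toy_plate_mask(w = 1040, h = 840, thick = 40, pitch = 20,
                        tick_len = 60, tick_w = 5)
  sc2 <- read_tick_scale(big, extract_leaf_and_frame(big)$frame)
  expect_equal(sc2$px_per_mm_x, 20)
  # a tick-free frame is unreadable
  bare <- toy_plate_mask(tick_len = 0)
  expect_error(read_tick_scale(bare, extract_leaf_and_frame(bare)$frame),
               class = "leafrect_scale_unreadable")
})

test_that("tick-count length rule matches the worked examples", {
  ticks <- seq(100, 400, by = 10)   # 1-mm ruler at 10 px/mm
  sc <- structure(list(top_tick_xs = ticks, left_tick_ys = ticks,
                       mm_per_tick = 1, px_per_mm_x = 10, px_per_mm_y = 10),
                  class = "tick_scale")
  span <- function(lo, hi) leafrect:::ruler_span_mm(lo, hi, ticks, 1, 10)
  # edges exactly on ticks: 30 pitches, zero fractions
  expect_equal(span(100, 400), 30)
  # edges half a pitch beyond the nearest inner ticks, 29 ticks inside
  expect_equal(span(115, 405), (29 - 1) * 1 + 0.5 + 0.5)
  # a span narrower than one pitch is fractional only
  expect_equal(span(102, 108), 0.6)
  expect_lt(span(101, 109), 1)
  # tie tolerance: an edge within 0.5 px of a tick counts it with no fraction
  expect_equal(span(100.4, 399.6), 30)
  # spans beyond the ruler fail
  expect_error(span(10, 200), class = "leafrect_out_of_range")
  # full rect interface
  rect <- bounding_rect(matrix(c(120, 380, 150, 350), 2, 2))
  lw <- length_width_from_ticks(rect, sc)
  expect_equal(lw$length_mm, 26)
  expect_equal(lw$width_mm, 20)
})

test_that("pixel counts match the worked square and the flood-fill oracle", {
  sq <- matrix(FALSE, 30, 30); sq[6:15, 6:15] <- TRUE
  ct <- leafrect:::contour_from_component(sq)
  st <- pixel_counts(ct, bounding_rect(ct))
  expect_equal(c(st$Pt, st$Pc, st$Prt, st$Pct), c(100, 36, 100, 36))
  # interior holes (lesions/wormholes) are filled before counting
  holed <- sq; holed[8:9, 9:10] <- FALSE
  sth <- pixel_counts(leafrect:::contour_from_component(holed),
                      bounding_rect(ct))
  expect_equal(sth$Pt, 100)
  # random blobs vs the border flood-fill oracle, masks up to 64 x 64
  for (seed in 1:12) {
    set.seed(seed)
    blob <- random_blob(sample(16:64, 1), sample(16:64, 1))
    ct <- leafrect:::contour_from_component(blob)
    expect_identical(ct$pixel_count_interior, as.integer(interior_bruteforce(blob)))
  }
  expect_error(contour_stats(0, 1, 1, 1), class = "leafrect_invalid_stats")
  expect_error(contour_stats(10, 4, 5, 8), class = "leafrect_invalid_stats")
})

test_that("area and perimeter ratios follow the reference-rectangle formulas", {
  # leaf fills its rectangle exactly
  st <- contour_stats(Pt = 2500, Pc = 196, Prt = 2500, Pct = 196)
  ap <- area_perimeter(st, Lr = 50, Wr = 50)
  expect_equal(ap$area_cm2, 25)
  expect_equal(ap$perimeter_cm, 20)
  # direct substitution: S = Sr * Pt / Prt
  st2 <- contour_stats(Pt = 5000, Pc = 300, Prt = 10000, Pct = 400)
  ap2 <- area_perimeter(st2, Lr = 60, Wr = 40)
  expect_equal(ap2$area_cm2, 24 * 5000 / 10000)
  expect_equal(ap2$rect_area_cm2, 24)
  expect_equal(ap2$perimeter_cm, 20 * 300 / 400)
  expect_equal(ap2$rect_perimeter_cm, 20)
  expect_error(area_perimeter(st2, Lr = 0, Wr = 40),
               class = "leafrect_invalid_parameter")
})

test_that("full pipeline measures the square scene and survives tilt", {
  ts <- test_scene(shape = "square")
  m <- measure_scene(ts)
  expect_lt(abs(rel_err_pct(m$area_cm2, 25)), 1)
  expect_lt(abs(rel_err_pct(m$perimeter_cm, 20)), 1)
  expect_lt(abs(rel_err_pct(m$length_mm, 50)), 1)
  expect_lt(abs(rel_err_pct(m$width_mm, 50)), 1)
  ts30 <- test_scene(shape = "square", tilt_deg = 30)
  m30 <- measure_scene(ts30)
  expect_lt(abs(rel_err_pct(m30$area_cm2, 25)), 2)
  # a scene without a plate frame fails with a stage-labelled error
  plain <- raster_image(array(rep(c(40, 200, 40), each = 400), c(20, 20, 3)))
  err <- tryCatch(measure(plain, leafrect_config()), error = function(e) e)
  expect_s3_class(err, "leafrect_error")
})

test_that("an axis-aligned rectangle acts as its own reference (self-reference)", {
  ts <- test_scene(shape = "rectangle")   # 60 x 40 mm -> >= 200 px per side
  m <- measure_scene(ts)
  expect_lt(abs(rel_err_pct(m$area_cm2, 24)), 0.5)
  expect_gt(m$stats$Pt / m$stats$Prt, 0.99)
})

test_that("measured area grows monotonically with disc radius", {
  a <- vapply(c(40, 50, 60), function(d) {
    ts <- test_scene(shape = "circle", diameter_mm = d)
    measure_scene(ts)$area_cm2
  }, 0)
  expect_true(all(diff(a) > 0))
})

test_that("interior holes do not change the measured area", {
  ts <- test_scene(shape = "circle")
  cfg <- config_for_scene(ts$spec)
  m0 <- measure_scene(ts)
  # punch holes (~6% of the leaf) into the rectified mask and re-run the
  # contour stage directly
  pcfg <- do.call(preprocess_config, cfg$preprocess)
  mask_raw <- preprocess(ts$scene$image, pcfg)
  vp <- virtual_plate(120, 90)
  H <- estimate_homography(detect_plate_quad(mask_raw), vp)
  mask <- binarize(rectify(attr(mask_raw, "gray"), H, vp), pcfg)
  comp0 <- extract_leaf_and_frame(mask)
  lb <- bounding_rect(comp0$leaf)
  holey <- unclass(mask)
  cx <- round((lb$x_min + lb$x_max) / 2); cy <- round((lb$y_min + lb$y_max) / 2)
  for (off in c(-60, 0, 60)) {
    holey[(cx + off - 20):(cx + off + 20) + 1, (cy - 20):(cy + 20) + 1] <- 0L
  }
  comp1 <- extract_leaf_and_frame(binary_mask(holey))
  st0 <- pixel_counts(comp0$leaf, bounding_rect(comp0$leaf))
  st1 <- pixel_counts(comp1$leaf, bounding_rect(comp1$leaf))
  expect_lt(abs(st1$Pt / st0$Pt - 1) * 100, 0.2)
})

test_that("measured area is stable across rendering resolution", {
  a <- vapply(c(800, 1600), function(wpx) {
    ts <- test_scene(shape = "circle", image_width_px = wpx)
    measure_scene(ts)$area_cm2
  }, 0)
  expect_lt(abs(a[2] / a[1] - 1) * 100, 0.5)
})
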