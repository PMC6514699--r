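test_that("silhouette ground truth is internally consistent", {
  # regular shapes carry analytic truths
  sq <- make_silhouette(scene_spec(shape = "square", side_mm = 50))
  expect_equal(sq$true_area_cm2, 25)
  expect_equal(sq$true_perimeter_cm, 20)
  ci <- make_silhouette(scene_spec(shape = "circle", diameter_mm = 60))
  expect_equal(ci$true_area_cm2, pi * 9, tolerance = 1e-12)
  expect_equal(ci$true_perimeter_cm, 6 * pi, tolerance = 1e-12)
  # the dense render polygon integrates to the analytic circle area (16384-gon)
  expect_lt(abs(poly_area(ci$poly) / 100 - pi * 9) / (pi * 9), 1e-6)
  tr <- make_silhouette(scene_spec(shape = "triangle", base_mm = 60, height_mm = 60))
  expect_equal(tr$true_area_cm2, 18)
  expect_equal(tr$true_perimeter_cm, (60 + 2 * sqrt(30^2 + 60^2)) / 10)
  # leaf templates: shoelace integral converges (half-density polygon agrees
  # to < 0.01%) and matches the requested area
  for (tpl in c("heart", "oval", "serrated", "slender")) {
    area <- if (tpl == "slender") 12 else 20  # slender = high aspect ratio
    sp <- scene_spec(shape = "leaf", leaf_template = tpl, leaf_area_cm2 = area,
                     plate_width_mm = 160, plate_height_mm = 120, seed = 4)
    sil <- make_silhouette(sp)
    expect_equal(sil$true_area_cm2, area, tolerance = 1e-9)
    half <- sil$poly[seq(1, nrow(sil$poly), by = 2), ]
    expect_lt(abs(poly_area(half) / poly_area(sil$poly) - 1), 1e-4)
  }
})

test_that("shapes that would touch the tick marks are rejected", {
  expect_error(make_silhouette(scene_spec(shape = "square", side_mm = 115)),
               class = "leafrect_invalid_spec")
  expect_error(scene_spec(tilt_deg = 75), class = "leafrect_invalid_spec")
  expect_error(scene_spec(plate_width_mm = -1), class = "leafrect_invalid_spec")
})

test_that("rendering is deterministic and seeds only perturb noise and leaves", {
  sp <- scene_spec(shape = "leaf", leaf_template = "serrated", noise_sd = 3,
                   image_width_px = 400)
  r1 <- render_scene(sp)
  r2 <- render_scene(sp)
  expect_identical(unclass(r1$image), unclass(r2$image))
  # a different seed changes the leaf outline but not a regular shape's truth
  sp2 <- scene_spec(shape = "leaf", leaf_template = "serrated", noise_sd = 3,
                    image_width_px = 400, seed = 9)
  r3 <- render_scene(sp2)
  expect_false(isTRUE(all.equal(r3$truth$true_length_mm, r1$truth$true_length_mm)))
  c1 <- render_scene(scene_spec(shape = "circle", image_width_px = 400, seed = 1))
  c2 <- render_scene(scene_spec(shape = "circle", image_width_px = 400, seed = 2))
  expect_identical(c1$truth$true_area_cm2, c2$truth$true_area_cm2)
})

test_that("the camera homography is a pure scale+translation when frontal", {
  r <- test_scene(shape = "square", tilt_deg = 0)$scene
  H <- r$truth$applied_homography
  expect_equal(c(H$B, H$D, H$G, H$H), rep(0, 4), tolerance = 1e-12)
  expect_equal(H$A, H$E, tolerance = 1e-12)
  # tilted: stored corners equal the homography applied to the plate corners
  r30 <- test_scene(shape = "square", tilt_deg = 30)$scene
  corners_mm <- rbind(c(0, 0), c(120, 0), c(120, 90), c(0, 90))
  expect_equal(apply_homography(r30$truth$applied_homography, corners_mm),
               r30$truth$true_corner_px, tolerance = 1e-6)
})

test_that("degradations move pixels the way they should", {
  base <- test_scene(shape = "circle")$scene
  noisy <- render_scene(scene_spec(shape = "circle", image_width_px = 800,
                                   noise_sd = 3, seed = 5))
  expect_gt(stats::sd(as.numeric(noisy$image[, , 1]) -
                        as.numeric(base$image[, , 1])), 1)
  shadowed <- render_scene(scene_spec(shape = "circle", image_width_px = 800,
                                      edge_shadow_px = 2))
  expect_lt(mean(shadowed$image), mean(base$image))  # dark band added
})

test_that("run_experiment sweeps grids and aggregates relative errors", {
  empty <- run_experiment(data.frame())
  expect_equal(nrow(empty$results), 0)
  ex <- run_experiment(data.frame(shape = c("square", "circle")),
                       spec_defaults = list(image_width_px = 800))
  area <- ex$results[ex$results$parameter == "area_cm2", ]
  expect_equal(area$status, rep("ok", 2))
  expect_lt(mean(abs(area$rel_err_pct)), 1)
  expect_true(all(c("mean_rel_err_pct", "max_rel_err_pct") %in%
                    names(ex$summary)))
  # failures are reported as rows, not raised
  bad <- run_experiment(data.frame(shape = "square", side_mm = 115),
                        spec_defaults = list(image_width_px = 400))
  expect_equal(bad$results$status, "failed")
  expect_match(bad$results$message, "does not fit")
})

test_that("area error grows from frontal to strongly tilted views", {
  err <- vapply(c(0, 45), function(tilt) {
    e <- vapply(c("square", "circle"), function(shp) {
      ts <- test_scene(shape = shp, tilt_deg = tilt)
      abs(rel_err_pct(measure_scene(ts)$area_cm2, ts$scene$truth$true_area_cm2))
    }, 0)
    mean(e)
  }, 0)
  expect_gte(err[2], err[1])
})
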