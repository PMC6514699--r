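test_that("plate_quad validates and canonically orders corners", {
  q <- plate_quad(rbind(c(90, 10), c(10, 80), c(10, 10), c(90, 80)))
  expect_equal(q$corners,
               rbind(c(10, 10), c(90, 10), c(90, 80), c(10, 80)))
  expect_error(plate_quad(rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1))),
               class = "leafrect_invalid_input")  # collinear
  expect_error(plate_quad(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))),
               class = "leafrect_invalid_input")  # duplicate
})

test_that("homography estimation recovers identity, translation and random warps", {
  vp <- virtual_plate(120, 90, px_per_mm = 10, margin_mm = 5)
  # identity mapping
  H <- estimate_homography(plate_quad(vp$corners), vp)
  expect_equal(c(H$A, H$E), c(1, 1), tolerance = 1e-9)
  expect_equal(c(H$B, H$C, H$D, H$F, H$G, H$H), rep(0, 6), tolerance = 1e-9)
  # pure translation: image shifted +10 px in x maps back with C = -10
  Ht <- estimate_homography(plate_quad(sweep(vp$corners, 2, c(-10, 0))), vp)
  expect_equal(c(Ht$A, Ht$E, Ht$C, Ht$G, Ht$H), c(1, 1, -10, 0, 0),
               tolerance = 1e-9)
  # random projective warps: the estimate is M^-1 after lambda normalization
  for (seed in 1:8) {
    set.seed(seed)
    M <- rbind(c(1 + rnorm(1, 0, 0.1), rnorm(1, 0, 0.1), rnorm(1, 0, 50)),
               c(rnorm(1, 0, 0.1), 1 + rnorm(1, 0, 0.1), rnorm(1, 0, 50)),
               c(rnorm(1, 0, 1e-4), rnorm(1, 0, 1e-4), 1))
    warped <- apply_homography(M, vp$corners)
    Hw <- estimate_homography(plate_quad(warped), vp)
    Minv <- solve(M); Minv <- Minv / Minv[3, 3]
    expect_equal(homography_matrix(Hw), Minv, tolerance = 1e-6)
    # round trip: estimated homography composed with M is the identity
    comp <- homography_matrix(Hw) %*% M
    expect_equal(comp / comp[3, 3], diag(3), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate correspondences raise singular-system errors", {
  vp <- virtual_plate(100, 80)
  collinearish <- structure(list(corners = rbind(c(0, 0), c(50, 0), c(100, 0),
                                                 c(50, 1e-13))),
                            class = "plate_quad")
  expect_error(estimate_homography(collinearish, vp),
               class = "leafrect_singular_system")
  expect_error(homography(1, 0, 0, 0, 1, 0, 0, -Inf),
               class = "leafrect_invalid_parameter")
  expect_error(homography_from_matrix(matrix(0, 3, 3)),
               class = "leafrect_singular_system")
})

test_that("homography JSON serialization round trips", {
  H <- homography(1.2, 0.01, -30, -0.02, 0.9, 12, 1e-4, -2e-4)
  tf <- withr::local_tempfile(fileext = ".json")
  homography_to_json(H, tf)
  H2 <- homography_from_json(tf)
  expect_equal(homography_matrix(H2), homography_matrix(H), tolerance = 1e-12)
})

test_that("plate corners are detected within 1 px on frontal and warped renders", {
  for (tilt in c(0, 20)) {
    ts <- test_scene(shape = "square", tilt_deg = tilt)
    mask <- preprocess(ts$scene$image)
    q <- detect_plate_quad(mask)
    err <- sqrt(rowSums((q$corners - ts$scene$truth$true_corner_px)^2))
    expect_lt(max(err), 1)
  }
  expect_error(detect_plate_quad(binary_mask(matrix(0L, 50, 50))),
               class = "leafrect_plate_not_found")
})

test_that("the Hough-line detector locates the same corners", {
  ts <- test_scene(shape = "square", tilt_deg = 20)
  mask <- preprocess(ts$scene$image)
  q <- detect_plate_quad(mask, method = "hough")
  err <- sqrt(rowSums((q$corners - ts$scene$truth$true_corner_px)^2))
  expect_lt(max(err), 1.5)
})

test_that("corner reprojection stays below 1 px across the 0-45 degree range", {
  # full operating resolution: reprojection is measured on the 10 px/mm
  # rectified grid, so halving the capture resolution doubles the residual
  vp <- virtual_plate(120, 90)
  for (tilt in c(0, 15, 30, 45)) {
    ts <- test_scene(shape = "square", tilt_deg = tilt, image_width_px = 1600)
    mask <- preprocess(ts$scene$image)
    q <- detect_plate_quad(mask)
    H <- estimate_homography(q, vp)
    # residual of the ground-truth corners after calibration
    reproj <- sqrt(rowSums((apply_homography(H, ts$scene$truth$true_corner_px) -
                              vp$corners)^2))
    expect_lt(max(reproj), 1)
    # the detected corners themselves map onto the virtual corners exactly
    fit <- sqrt(rowSums((apply_homography(H, q$corners) - vp$corners)^2))
    expect_lt(max(fit), 0.5)
  }
})

test_that("rectification preserves straight lines", {
  ts <- test_scene(shape = "square", tilt_deg = 30)
  mask <- preprocess(ts$scene$image)
  vp <- virtual_plate(120, 90)
  H <- estimate_homography(detect_plate_quad(mask), vp)
  tc <- ts$scene$truth$true_corner_px
  # sample the true top edge of the frame in the distorted image
  tseq <- seq(0, 1, length.out = 25)
  src <- cbind(tc[1, 1] + tseq * (tc[2, 1] - tc[1, 1]),
               tc[1, 2] + tseq * (tc[2, 2] - tc[1, 2]))
  dst <- apply_homography(H, src)
  fit <- stats::lm.fit(cbind(1, dst[, 1]), dst[, 2])
  expect_lt(max(abs(fit$residuals)), 0.5)
})

test_that("rectifying a tilted scene reproduces the frontal view", {
  vp <- virtual_plate(120, 90)
  rectified <- lapply(c(0, 30), function(tilt) {
    ts <- test_scene(shape = "circle", tilt_deg = tilt)
    mask <- preprocess(ts$scene$image)
    H <- estimate_homography(detect_plate_quad(mask), vp)
    as_matrix_test(rectify(attr(mask, "gray"), H, vp))
  })
  # compare inside the frame, away from the high-gradient edges
  inner <- list(x = 80:1120, y = 80:820)
  d <- abs(rectified[[1]][inner$x, inner$y] - rectified[[2]][inner$x, inner$y])
  expect_lt(mean(d), 2)
})

test_that("rectify output geometry follows the virtual plate and fills all pixels", {
  vp <- virtual_plate(30, 20, px_per_mm = 2, margin_mm = 0)
  img <- raster_image(matrix(runif(80 * 60, 0, 255), 80, 60))
  out <- rectify(img, homography(1, 0, 0, 0, 1, 0, 0, 0), vp)
  expect_equal(dim(out), c(60, 40))
  # identity homography crops the source region
  expect_equal(as_matrix_test(out), as_matrix_test(img)[1:60, 1:40],
               tolerance = 1e-9)
})
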