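grid_square <- data.frame(i = c(0, 1, 0, 1), j = c(0, 0, 1, 1),
                          x_px = c(0, 100, 0, 100), y_px = c(0, 0, 100, 100))

test_that("grid calibration recovers the pixel scale by similarity fit", {
  sc <- calibrate_scale(grid_square, grid_pitch_mm = 1)
  expect_equal(sc$mm_per_px, 0.01)
  expect_equal(sc$fit_residual_px, 0)

  # 0.5 mm pitch at 200 px spacing -> 0.0025 mm/px
  g2 <- within(grid_square, {x_px <- x_px * 2; y_px <- y_px * 2})
  sc2 <- calibrate_scale(g2, grid_pitch_mm = 0.5)
  expect_equal(sc2$mm_per_px, 0.0025)

  # rotation of the grid does not change the recovered scale
  th <- 0.4
  g3 <- grid_square
  g3$x_px <- cos(th) * grid_square$x_px - sin(th) * grid_square$y_px + 17
  g3$y_px <- sin(th) * grid_square$x_px + cos(th) * grid_square$y_px - 4
  sc3 <- calibrate_scale(g3, grid_pitch_mm = 1)
  expect_equal(sc3$mm_per_px, 0.01, tolerance = 1e-12)
  expect_equal(sc3$rotation_rad, th, tolerance = 1e-12)

  # degenerate inputs
  expect_error(calibrate_scale(data.frame(i = 0:2, j = 0, x_px = c(0, 50, 100),
                                          y_px = 0), 1), "collinear")
  expect_error(calibrate_scale(grid_square[1:2, ], 1), "at least 3")
  expect_error(calibrate_scale(grid_square, -1), "grid_pitch_mm")
})

test_that("planimetric area is pixel count times squared scale", {
  sc <- pixel_scale(0.01)
  mask <- matrix(FALSE, 200, 200)
  mask[51:150, 51:150] <- TRUE  # 10,000 px
  expect_equal(measure_area_2d(mask, sc), 1.0)
  expect_warning(a0 <- measure_area_2d(matrix(FALSE, 5, 5), sc), "empty")
  expect_equal(a0, 0)

  # invariance to translation and 90-degree rotation
  mask2 <- matrix(FALSE, 200, 200)
  mask2[21:120, 61:160] <- TRUE
  expect_equal(measure_area_2d(mask2, sc), measure_area_2d(mask, sc))
  expect_equal(measure_area_2d(t(mask2), sc), measure_area_2d(mask2, sc))
})

test_that("phantom cap photographed pole-on matches the analytic silhouette", {
  ph <- make_head_phantom(phantom_params(eye_radius_mm = 1,
                                         dra_angular_radius_rad = 0.2))
  sc <- pixel_scale(1 / ph$pose$scale_px_per_mm)
  a <- measure_area_2d(ph$rendered_mask, sc)
  expect_lt(abs(a - pi * sin(0.2)^2) / (pi * sin(0.2)^2), 0.02)
})

test_that("image rescaling leaves mm-valued areas unchanged within 2%", {
  ph <- default_phantom()
  for (k in c(0.5, 2)) {
    img <- round(c(480, 480) * k)
    pose_k <- pose_toward(c(0, 0, 1), ph$pose$scale_px_per_mm * k, img)
    rv <- render_view(ph, pose_k, img)
    a_k <- measure_area_2d(rv$mask, pixel_scale(1 / pose_k$scale_px_per_mm))
    a_1 <- measure_area_2d(ph$rendered_mask,
                           pixel_scale(1 / ph$pose$scale_px_per_mm))
    expect_lt(abs(a_k - a_1) / a_1, 0.02)
  }
})

test_that("inter-tegular distance is Euclidean distance times scale", {
  sc <- pixel_scale(0.01)
  expect_equal(measure_itd(c(0, 0), c(300, 400), sc), 5)
  expect_warning(d0 <- measure_itd(c(10, 10), c(10, 10), sc), "coincide")
  expect_equal(d0, 0)
  # round trip through a known ITD
  itd <- 4.321
  expect_equal(measure_itd(c(0, 0), c(itd / 0.01, 0), sc), itd)
})

test_that("size classes use the published half-open ITD bins", {
  expect_equal(classify_size(3.0), "small")
  expect_equal(classify_size(4.0), "medium")
  expect_equal(classify_size(5.0), "large")
  # shared endpoints go to the upper bin; the last bin is closed
  expect_equal(classify_size(3.902), "medium")
  expect_equal(classify_size(4.839), "large")
  expect_equal(classify_size(5.776), "large")
  expect_equal(classify_size(2.0), "out_of_range")
  expect_equal(classify_size(6.0), "out_of_range")
  expect_error(classify_size(-1), "positive")
})
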