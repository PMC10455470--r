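test_that("phantom truth areas follow the spherical-cap formula", {
  # empty cap
  ph0 <- make_head_phantom(phantom_params(eye_radius_mm = 1,
                                          dra_angular_radius_rad = 0),
                           subdivisions = 3L)
  expect_equal(ph0$true_dra_area_mm2, 0)
  expect_equal(sum(ph0$rendered_mask), 0)

  # hemisphere cap on a unit sphere: analytic area 2*pi
  ph_half <- make_head_phantom(phantom_params(eye_radius_mm = 1,
                                              dra_angular_radius_rad = pi / 2))
  expect_equal(ph_half$true_dra_area_mm2, 2 * pi)
  expect_lt(abs(region_area(ph_half$mesh, "DRA") - 2 * pi) / (2 * pi), 0.01)

  # generic cap: mesh-summed face area vs analytic formula
  ph <- make_head_phantom(phantom_params(eye_radius_mm = 1.2,
                                         dra_angular_radius_rad = 0.25))
  truth <- spherical_cap_area(1.2, 0.25)
  expect_lt(abs(region_area(ph$mesh, "DRA") - truth) / truth, 0.01)
  expect_lte(ph$true_dra_area_mm2, ph$true_eye_area_mm2)
})

test_that("phantom parameter validation names the offending field", {
  expect_error(phantom_params(eye_radius_mm = -1), "eye_radius_mm")
  expect_error(phantom_params(dra_angular_radius_rad = 2), "dra_angular_radius_rad")
  expect_error(phantom_params(facet_pitch_mm = 0), "facet_pitch_mm")
  expect_error(phantom_params(layer_thicknesses_um = c(1, -2, 3)),
               "layer_thicknesses_um")
  collinear <- rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3))
  rownames(collinear) <- c("a", "b", "c")
  expect_error(phantom_params(ocelli_mm = collinear), "collinear")
})

test_that("rendered views obey the orthographic projection model", {
  ph <- default_phantom()
  # identity-style pose: scale s, centered offset
  s <- 100
  pose <- camera_pose(diag(3), s, c(240, 240))
  pt <- matrix(c(0.3, -0.2, 0.5), 1)
  pr <- project_points(pose, pt)
  expect_equal(as.numeric(pr$px), c(s * 0.3 + 240, s * -0.2 + 240))
  expect_equal(pr$depth, 0.5)

  # pole-on cap silhouette is a disc of radius ~ s * R * sin(theta)
  mask <- ph$rendered_mask
  r_px <- sqrt(sum(mask) / pi)
  r_true <- ph$pose$scale_px_per_mm * ph$params$eye_radius_mm *
    sin(ph$params$dra_angular_radius_rad)
  expect_lt(abs(r_px - r_true), 1)

  # projection never exceeds the 3D cap area, under several poses
  for (tilt in c(0, 0.15, 0.3)) {
    pose_t <- pose_toward(c(0, 0, 1), ph$pose$scale_px_per_mm, c(480, 480),
                          tilt_rad = tilt)
    rv <- render_view(ph, pose_t, c(480, 480))
    plan <- sum(rv$mask) / pose_t$scale_px_per_mm^2
    expect_lte(plan, ph$true_dra_area_mm2)
  }

  # eye fully outside the frame is a render error
  pose_off <- camera_pose(diag(3), 100, c(-5000, -5000))
  expect_error(render_view(ph, pose_off, c(100, 100)), "render error")
})

test_that("volume phantoms have the constructed shell geometry", {
  vp <- histo_phantom()
  truth <- vp$truth
  # voxels outside the eye are background (noise-free check on radii)
  expect_equal(unname(truth$radii_um$non_DRA["outer"]), 160)
  # lens shell spans lens_thickness / voxel_size voxels
  expect_equal(
    (truth$radii_um$non_DRA["outer"] - truth$radii_um$non_DRA["lens_cone"]) / 1.625,
    18 / 1.625, ignore_attr = TRUE)
  # radial profile crosses exactly 3 transitions before the rhabdom
  # interior (bg->lens, lens->cone, cone->rhabdom), then rhabdom->interior
  d <- c(0.3, 0.2, 0.93)
  prof <- extract_profile(vp$volume, 0.18 * d / sqrt(sum(d^2)),
                          -d, 140, 1.625 / 2)
  m <- measure_layer(prof, 1.625 / 2, dynamic_range = 65535)
  expect_equal(length(m$boundaries_um), 4L)
  # a layer thinner than 3 voxels is a resolution error
  pp_thin <- phantom_params(eye_radius_mm = 0.16,
                            layer_thicknesses_um = c(lens = 3, cone = 36, rhabdom = 50))
  expect_error(make_volume_phantom(pp_thin), "resolution")
})

test_that("allometric cohort generation is exact and reproducible", {
  # noise-free identity: sqrt(area) equals ITD exactly
  coh <- make_allometric_cohort(n = 10, slope = 1, intercept = 0,
                                noise_sd = 0, seed = 3)
  expect_equal(sqrt(coh$dra_area_mm2), coh$itd_mm)

  # noise-free recovery of a non-trivial slope to machine precision
  coh8 <- make_allometric_cohort(n = 12, slope = 0.8, noise_sd = 0, seed = 4)
  fit <- fit_allometry(coh8$itd_mm, coh8$dra_area_mm2)
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)

  # determinism and parameter validation
  expect_identical(make_allometric_cohort(seed = 99),
                   make_allometric_cohort(seed = 99))
  expect_error(make_allometric_cohort(noise_sd = -1), "noise_sd")
  expect_error(make_allometric_cohort(n = 2), "at least 3")
})

test_that("manual-annotation emulation perturbs only the mask boundary", {
  ph <- default_phantom()
  ann <- annotate_mask(ph$rendered_mask, sd_px = 2, seed = 7)
  # areas agree within a few percent, but the masks are not identical
  expect_lt(abs(sum(ann) - sum(ph$rendered_mask)) / sum(ph$rendered_mask), 0.15)
  expect_gt(sum(xor(ann, ph$rendered_mask)), 0)
  # overlap stays high (boundary-only perturbation)
  expect_gt(sum(ann & ph$rendered_mask) / sum(ann | ph$rendered_mask), 0.85)
  expect_identical(annotate_mask(ph$rendered_mask, seed = 5),
                   annotate_mask(ph$rendered_mask, seed = 5))
})
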