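test_that("slice extraction samples the volume faithfully", {
  # constant field -> constant slice
  vc <- volume_image(array(7, c(20, 20, 20)), 1)
  pl <- slice_plane(c(0.009, 0.009, 0.009), c(1, 0, 0), c(0, 1, 0),
                    c(0.01, 0.01), 1)
  sl <- extract_slice(vc, pl)
  expect_true(all(sl == 7))

  # axis-aligned plane through voxel centers equals the array section
  arr <- array(runif(20^3), c(20, 20, 20))
  v <- volume_image(arr, 1)
  k <- 11
  plk <- slice_plane(c(0.0095, 0.0095, (k - 1) * 0.001), c(1, 0, 0), c(0, 1, 0),
                     c(0.019, 0.019), 1)
  slk <- extract_slice(v, plk)
  expect_equal(dim(slk), c(20, 20))
  expect_equal(unclass(slk)[1:20, 1:20], t(arr[, , k]), ignore_attr = TRUE,
               tolerance = 1e-12)

  # plane outside the volume is an empty-slice error; undersampling refused
  pl_out <- slice_plane(c(1, 1, 1), c(1, 0, 0), c(0, 1, 0), c(0.01, 0.01), 1)
  expect_error(extract_slice(v, pl_out), "empty slice")
  pl_us <- slice_plane(c(0.01, 0.01, 0.01), c(1, 0, 0), c(0, 1, 0),
                       c(0.01, 0.01), 1.5)
  expect_error(extract_slice(v, pl_us), "undersampling")
  expect_error(slice_plane(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1), 1),
               "orthogonal")
})

test_that("layered slab sliced obliquely recovers true thickness", {
  # slab with layers stacked along z: boundaries at known z positions
  n <- 60
  arr <- array(1000, c(n, n, n))
  arr[, , 21:35] <- 30000   # 15-voxel layer
  arr[, , 36:60] <- 60000
  v <- volume_image(arr, 1000)
  # slice plane containing the layer normal but with axes at 30 degrees to
  # it; the thickness is measured along the in-slice projection of the
  # normal, which here is the normal itself
  th <- pi / 6
  u <- c(sin(th), 0, cos(th))
  w <- c(cos(th), 0, -sin(th))
  center <- c(29.5, 29.5, 29.5)
  pl <- slice_plane(center, u, w, c(55, 55), 1000)
  sl <- extract_slice(v, pl)
  # direction of z in (u, v) slice coordinates
  dz <- c(sum(c(0, 0, 1) * u), sum(c(0, 0, 1) * w))
  prof <- slice_line(sl, dir_uv = dz, step_um = 500)
  m <- measure_layer(prof, 500, dynamic_range = 65535)
  expect_equal(length(m$thicknesses_um), 1L)
  expect_lt(abs(m$thicknesses_um - 15000), 1000)  # within 1 voxel
})

test_that("rhabdom continuity QC detects gaps at the stated tolerance", {
  good <- ring_slice()
  qc <- check_rhabdom_continuity(good, c(50, 150), gap_tolerance_um = 3)
  expect_true(qc$pass)
  expect_equal(length(qc$gaps_um), 0L)

  # a ~10 um arc gap at radius 30 px, 1 um/px: 10 um is ~19 degrees
  gap <- ring_slice(gap_deg = c(10, 29.1))
  qf <- check_rhabdom_continuity(gap, c(50, 150), gap_tolerance_um = 3.25)
  expect_false(qf$pass)
  expect_equal(length(qf$gaps_um), 1L)
  expect_lt(abs(qf$gaps_um - 10), 2.5)

  # monotone in tolerance: raising it above the gap passes the same slice
  qp <- check_rhabdom_continuity(gap, c(50, 150), gap_tolerance_um = 14)
  expect_true(qp$pass)

  # band spec matching nothing is a QC error, distinct from fail
  expect_error(check_rhabdom_continuity(good, c(1000, 2000)), "QC error")
})

test_that("boundary detection and manual mode measure as specified", {
  prof <- c(rep(0, 11), rep(100, 15), rep(30, 10))
  m <- measure_layer(prof, 1, dynamic_range = 100)
  expect_equal(m$boundaries_um, c(10.5, 25.5), tolerance = 1e-6)
  expect_equal(m$thicknesses_um, 15, tolerance = 1e-6)
  expect_error(measure_layer(rep(5, 50), 1, dynamic_range = 100),
               "measurement failure")
  expect_equal(measure_manual(c(0, 0), c(3, 4), um_per_sample = 1), 5)
})

test_that("phantom layer thicknesses are recovered within one voxel", {
  vp <- histo_phantom()
  # non-DRA direction (polar angle 0.8 > theta + 5 rows)
  d <- c(sin(0.8), 0.02, cos(0.8)); d <- d / sqrt(sum(d^2))
  prof <- extract_profile(vp$volume, d * 0.18, -d, 140, 1.625 / 2)
  m <- measure_layer(prof, 1.625 / 2, dynamic_range = 65535)
  expect_lt(max(abs(diff(m$boundaries_um[1:4]) - c(18, 36, 50))), 1.625)
  # DRA direction: cone layer built 20% thinner
  d2 <- c(0.05, 0.03, 0.99); d2 <- d2 / sqrt(sum(d2^2))
  prof2 <- extract_profile(vp$volume, d2 * 0.18, -d2, 140, 1.625 / 2)
  m2 <- measure_layer(prof2, 1.625 / 2, dynamic_range = 65535)
  expect_lt(max(abs(diff(m2$boundaries_um[1:4]) - c(18, 0.8 * 36, 50))), 1.625)
})

test_that("3D lens width measurements convert units and warn off-surface", {
  ph <- make_head_phantom(phantom_params(eye_radius_mm = 1), subdivisions = 3L)
  v1 <- ph$mesh$vertices[1, ]
  v2 <- ph$mesh$vertices[2, ]
  expect_warning(w0 <- measure_lens_width_3d(ph$mesh, v1, v1, voxel_size_um = 5),
                 "zero")
  expect_equal(w0, 0)
  w <- measure_lens_width_3d(ph$mesh, v1, v2, voxel_size_um = 50)
  expect_equal(w, sqrt(sum((v1 - v2)^2)) * 1000)
  expect_warning(measure_lens_width_3d(ph$mesh, v1 * 1.5, v2, voxel_size_um = 5),
                 "off the surface")
})

test_that("region bands follow the ommatidial-row definition geodesically", {
  ph <- make_head_phantom(phantom_params(eye_radius_mm = 1,
                                         dra_angular_radius_rad = 0.3,
                                         facet_pitch_mm = 0.025))
  mesh <- assign_region(ph$mesh, region_bands(0.025))
  cen <- face_centroids(mesh)
  ang <- acos(pmin(1, cen[, 3] / sqrt(rowSums(cen^2))))
  pick_at <- function(rows) {
    which.min(abs(ang - (0.3 + rows * 0.025 / 1)))
  }
  expect_equal(as.character(mesh$face_region[pick_at(3)]), "proximate")
  expect_equal(as.character(mesh$face_region[pick_at(10)]), "buffer")
  expect_equal(as.character(mesh$face_region[pick_at(25)]), "non_DRA")
  # faces inside the DRA keep their label; partition covers everything
  expect_true(all(mesh$face_region[ph$mesh$face_region == "DRA"] == "DRA"))
  expect_false(any(mesh$face_region == "unlabeled"))
  expect_error(assign_region(set_face_region(ph$mesh,
                                             seq_len(nrow(ph$mesh$faces)),
                                             "unlabeled"),
                             region_bands(0.025)), "no DRA")
  expect_error(region_bands(0.025, proximate_rows = 21), "proximate_rows")
})
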