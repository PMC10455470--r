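test_that("triangle-sum area matches closed forms", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(mesh_area(tri), 0.5)

  ph <- make_head_phantom(phantom_params(eye_radius_mm = 1))
  expect_lt(abs(mesh_area(ph$mesh) - 4 * pi) / (4 * pi), 0.01)

  # duplicating every face exactly doubles the area
  dup <- surface_mesh(ph$mesh$vertices, rbind(ph$mesh$faces, ph$mesh$faces))
  expect_equal(mesh_area(dup), 2 * mesh_area(ph$mesh))
})

test_that("isosurface extraction recovers analytic areas from labels", {
  vol <- ball_volume(20)
  m <- label_to_mesh(vol)
  expect_lt(abs(mesh_area(m) - 4 * pi * 20^2) / (4 * pi * 20^2), 0.03)

  arr <- array(0, c(60, 52, 56))
  arr[6:55, 7:46, 6:50] <- 1  # 50 x 40 x 45 voxel box
  bx <- label_to_mesh(volume_image(arr, 1000))
  true_box <- 2 * (50 * 40 + 40 * 45 + 45 * 50)
  expect_lt(abs(mesh_area(bx) - true_box) / true_box, 0.03)

  expect_error(label_to_mesh(volume_image(array(0, c(5, 5, 5)), 1)),
               "no foreground")
  # foreground touching the border warns about an open surface
  arr2 <- array(0, c(10, 10, 10)); arr2[1:5, 3:7, 3:7] <- 1
  expect_warning(label_to_mesh(volume_image(arr2, 1)), "border")
})

test_that("area is invariant under rigid motion and voxel refinement", {
  ph <- make_head_phantom(phantom_params(eye_radius_mm = 0.9),
                          subdivisions = 4L)
  R <- dramorph:::rotation_about(c(1, 2, 3), 0.77)
  rot <- surface_mesh(sweep(ph$mesh$vertices %*% t(R), 2, c(1, -2, 0.5), "+"),
                      ph$mesh$faces)
  expect_lt(abs(mesh_area(rot) - mesh_area(ph$mesh)) / mesh_area(ph$mesh), 1e-10)

  # same physical ball at two voxel sizes: < 2% change
  a1 <- mesh_area(label_to_mesh(ball_volume(16, voxel_size_um = 2)))
  a2 <- mesh_area(label_to_mesh(ball_volume(32, voxel_size_um = 1)))
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("region areas partition the total exactly", {
  ph <- make_head_phantom(phantom_params(dra_angular_radius_rad = 0.3))
  mesh <- assign_region(ph$mesh, region_bands(0.025))
  parts <- vapply(c("DRA", "proximate", "buffer", "non_DRA", "unlabeled"),
                  function(rg) region_area(mesh, rg), numeric(1))
  expect_equal(sum(parts), mesh_area(mesh))
  expect_equal(region_area(ph$mesh, "proximate"), 0)  # before banding
  expect_error(region_area(mesh, "fovea"), "unknown region")
})

test_that("PLY round trip preserves geometry and labels", {
  ph <- make_head_phantom(phantom_params(), subdivisions = 3L)
  mesh <- assign_region(ph$mesh, region_bands(0.025))
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, path)
  back <- read_ply(path)
  expect_equal(back$vertices, unname(mesh$vertices))
  expect_equal(back$faces, mesh$faces, ignore_attr = TRUE)
  expect_equal(as.character(back$face_region), as.character(mesh$face_region))
})

test_that("volume containers validate and crop consistently", {
  expect_error(volume_image(array(0, c(4, 4)), 1), "3D")
  expect_error(volume_image(array(0, c(4, 4, 4)), -1), "voxel_size_um")
  v <- volume_image(array(seq_len(4^3), c(4, 4, 4)), 1000, origin_mm = c(1, 2, 3))
  cr <- crop_volume(v, x = c(2, 3))
  expect_equal(dim(cr$data), c(2, 4, 4))
  expect_equal(cr$origin_mm, c(2, 2, 3))
  expect_equal(cr$data[1, 1, 1], v$data[2, 1, 1])
  expect_error(crop_volume(v, z = c(0, 2)), "out of bounds")
})
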