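test_that("pose estimation inverts the forward projection exactly", {
  ph <- default_phantom()
  lms <- landmark_set(dramorph:::phantom_landmarks_mm(ph$params),
                      ph$landmark_px)
  pe <- estimate_pose(lms, ph$mesh)
  expect_lt(pe$residual_px, 1e-6)
  expect_lt(dramorph:::rotation_angle_deg(pe$rotation, ph$pose$rotation), 1e-6)
  expect_equal(pe$scale_px_per_mm, ph$pose$scale_px_per_mm, tolerance = 1e-9)
  expect_false(pe$flagged)

  # identity configuration: 3D (x, y, z) maps to 2D (x, y)
  X <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), d = c(0.3, 0.4, 0.8))
  x2 <- X[, 1:2]
  pe_id <- estimate_pose(landmark_set(X, x2))
  pr <- project_points(pe_id, X)
  expect_lt(max(abs(pr$px - x2)), 1e-8)

  # collinear 3D landmarks are a degenerate configuration
  Xc <- rbind(a = c(0, 0, 0), b = c(1, 1, 1), c = c(2, 2, 2))
  expect_error(estimate_pose(landmark_set(Xc, Xc[, 1:2])), "collinear")
  expect_error(landmark_set(X[1:2, ], x2[1:2, ]), "at least 3")
})

test_that("noisy ocelli clicks still give sub-2-degree poses", {
  ph <- default_phantom()
  lmm <- dramorph:::phantom_landmarks_mm(ph$params)
  errs <- vapply(1:50, function(r) {
    lm2 <- ph$landmark_px +
      dramorph:::with_seed(7000 + r, matrix(rnorm(8, 0, 0.5), 4, 2))
    rownames(lm2) <- rownames(ph$landmark_px)
    pe <- estimate_pose(landmark_set(lmm, lm2), ph$mesh)
    dramorph:::rotation_angle_deg(pe$rotation, ph$pose$rotation)
  }, numeric(1))
  expect_gte(mean(errs < 2), 0.9)
})

test_that("mask projection labels exactly the visible faces it should", {
  ph <- default_phantom()
  blank <- set_face_region(ph$mesh, seq_len(nrow(ph$mesh$faces)), "unlabeled")

  # all-true mask labels exactly the front-facing faces of the convex eye
  full <- matrix(TRUE, 480, 480)
  lab_full <- project_mask(blank, ph$pose, full)
  view <- ph$pose$rotation[3, ]
  front <- rowSums(face_normals(blank) * rep(view, each = nrow(blank$faces))) < 0
  expect_equal(which(lab_full$face_region == "DRA"), which(front))

  # all-false mask labels nothing
  lab_none <- project_mask(blank, ph$pose, matrix(FALSE, 480, 480))
  expect_equal(sum(lab_none$face_region == "DRA"), 0L)

  # flagged poses are refused unless overridden
  bad <- ph$pose
  bad$flagged <- TRUE
  expect_error(project_mask(blank, bad, full), "flagged")
  expect_silent(project_mask(blank, bad, full, override = TRUE))
})

test_that("render-project-reproject round trip is near-lossless", {
  ph <- default_phantom()
  blank <- set_face_region(ph$mesh, seq_len(nrow(ph$mesh$faces)), "unlabeled")
  lab <- project_mask(blank, ph$pose, ph$rendered_mask)
  truth_set <- which(ph$mesh$face_region == "DRA")
  est_set <- which(lab$face_region == "DRA")
  iou_face <- length(intersect(truth_set, est_set)) /
    length(union(truth_set, est_set))
  expect_gte(iou_face, 0.95)

  back <- reproject_region(lab, ph$pose, "DRA", c(480, 480))
  iou_px <- sum(back & ph$rendered_mask) / sum(back | ph$rendered_mask)
  expect_gte(iou_px, 0.95)

  # masked 2D area never exceeds the labeled 3D surface area
  area_2d <- sum(ph$rendered_mask) / ph$pose$scale_px_per_mm^2
  expect_lte(area_2d, region_area(lab, "DRA") * (1 + 1e-6))
})

test_that("reprojection respects occlusion and empty regions", {
  ph <- default_phantom()
  expect_warning(
    empty <- reproject_region(ph$mesh, ph$pose, "non_DRA", c(100, 100)),
    "no faces")
  expect_false(any(empty))

  # a region on the far side of the eye is fully occluded
  far <- set_face_region(ph$mesh, seq_len(nrow(ph$mesh$faces)), "unlabeled")
  cen <- face_centroids(far)
  far_faces <- which(cen[, 3] < -0.9 * ph$params$eye_radius_mm)
  far <- set_face_region(far, far_faces, "DRA")
  m <- reproject_region(far, ph$pose, "DRA", c(480, 480))
  expect_false(any(m))
})
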