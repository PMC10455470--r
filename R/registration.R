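#' Scaled-orthographic camera pose
#'
#' Maps 3D mm coordinates to 2D pixel coordinates as
#' `px = scale_px_per_mm * (R X)[1:2] + offset_px`, with depth `(R X)[3]`
#' (smaller depth = closer to the camera). A stereomicroscope at long
#' working distance is near-telecentric, so a scaled-orthographic model is
#' used rather than full perspective; three ocelli cannot stably constrain
#' a perspective pose.
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param scale_px_per_mm positive scale.
#' @param offset_px length-2 pixel offset.
#' @param residual_px RMS reprojection residual over the landmarks used to
#'   estimate the pose (0 for a constructed pose).
#' @param flagged logical, `TRUE` when the residual exceeded the estimation
#'   threshold.
#' @export
camera_pose <- function(rotation, scale_px_per_mm, offset_px = c(0, 0),
                        residual_px = 0, flagged = FALSE) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) abort("rotation must be 3 x 3")
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    abort("rotation must be orthonormal with det +1")
  if (scale_px_per_mm <= 0) abort("scale_px_per_mm must be positive")
  structure(
    list(rotation = rotation, scale_px_per_mm = scale_px_per_mm,
         offset_px = as.numeric(offset_px), residual_px = residual_px,
         flagged = flagged, model = "scaled_orthographic"),
    class = "camera_pose"
  )
}

#' @export
print.camera_pose <- function(x, ...) {
  cat("<camera_pose> scaled orthographic, ",
      format(x$scale_px_per_mm, digits = 5), " px/mm\n", sep = "")
  cat("  offset (px):", paste(format(x$offset_px, digits = 5), collapse = ", "),
      " residual:", format(x$residual_px, digits = 4), "px",
      if (x$flagged) " [FLAGGED]" else "", "\n")
  invisible(x)
}

#' Project 3D points through a camera pose
#' @param pose a [camera_pose()].
#' @param pts_mm n x 3 matrix of mm coordinates.
#' @return list with `px` (n x 2 pixel coordinates, x = column, y = row)
#'   and `depth` (camera-space depth in mm).
#' @export
project_points <- function(pose, pts_mm) {
  pts_mm <- rbind(pts_mm)
  cam <- pts_mm %*% t(pose$rotation)
  px <- sweep(cam[, 1:2, drop = FALSE] * pose$scale_px_per_mm, 2,
              pose$offset_px, "+")
  list(px = px, depth = cam[, 3])
}

#' A pose looking along a given world direction
#'
#' Convenience constructor: the camera looks along `-direction` (so a
#' surface patch centered on `direction` from the origin faces the camera),
#' optionally tilted, with pixel offset at the image center.
#'
#' @param direction world direction that should face the camera.
#' @param scale_px_per_mm pixel scale.
#' @param image_size `(width, height)` in px used to center the view.
#' @param tilt_rad,tilt_axis optional tilt of the viewing direction.
#' @export
pose_toward <- function(direction, scale_px_per_mm, image_size,
                        tilt_rad = 0, tilt_axis = c(1, 0, 0)) {
  b <- orthobasis(direction)
  R <- rbind(b$e1, b$e2, -b$u)  # third row = view direction into the scene
  if (abs(det(R) - 1) > 1e-8) R[1, ] <- -R[1, ]
  if (tilt_rad != 0) R <- rotation_about(tilt_axis, tilt_rad) %*% R
  camera_pose(R, scale_px_per_mm, offset_px = image_size / 2)
}

#' Named landmark correspondences for pose estimation
#'
#' @param points_3d_mm named n x 3 matrix (rownames are landmark names,
#'   e.g. `ocellus_left`, `ocellus_median`, `ocellus_right`).
#' @param points_2d_px named n x 2 matrix of the same landmarks in the
#'   photograph (x = column, y = row).
#' @export
landmark_set <- function(points_3d_mm, points_2d_px) {
  p3 <- as.matrix(points_3d_mm)
  p2 <- as.matrix(points_2d_px)
  if (is.null(rownames(p3)) || is.null(rownames(p2)))
    abort("landmark matrices must have rownames")
  common <- intersect(rownames(p3), rownames(p2))
  if (length(common) < 3)
    abort("need at least 3 landmarks present in both 2D and 3D sets")
  structure(list(names = common,
                 points_3d_mm = p3[common, , drop = FALSE],
                 points_2d_px = p2[common, , drop = FALSE]),
            class = "landmark_set")
}

#' Estimate a scaled-orthographic pose from landmarks
#'
#' Least-squares orthographic factorization. For coplanar landmarks (the
#' generic case with three ocelli) the two reflection-related solutions are
#' disambiguated, when a mesh is supplied, by choosing the pose under which
#' the majority of eye faces point toward the camera; without a mesh the
#' solution with non-negative out-of-plane component for the first camera
#' axis is returned and the pose is marked `ambiguous`.
#'
#' @param landmarks a [landmark_set()].
#' @param mesh optional [surface_mesh()] used to resolve the reflection
#'   ambiguity of coplanar landmark configurations.
#' @param flag_threshold_px poses with RMS reprojection residual above this
#'   are flagged (default 5 px).
#' @return a [camera_pose()] with `residual_px` filled in; attribute
#'   `ambiguous` is `TRUE` if the reflection could not be resolved.
#' @export
estimate_pose <- function(landmarks, mesh = NULL, flag_threshold_px = 5) {
  stopifnot(inherits(landmarks, "landmark_set"))
  X <- landmarks$points_3d_mm
  x <- landmarks$points_2d_px
  n <- nrow(X)
  Xbar <- colMeans(X)
  xbar <- colMeans(x)
  Xc <- sweep(X, 2, Xbar)
  xc <- sweep(x, 2, xbar)
  sv <- svd(Xc)
  span <- vec_norm(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12) || span == 0)
    abort("degenerate landmark configuration: 3D landmarks are collinear")
  coplanar <- sv$d[3] < 1e-7 * sv$d[1]

  candidates <- list()
  if (!coplanar) {
    A <- t(qr.solve(Xc, xc))           # 2 x 3 affine projection
    sa <- svd(A)
    R12 <- sa$u %*% t(sa$v)            # nearest row-orthonormal 2 x 3
    s <- mean(sa$d[1:2])
    r3 <- cross3(R12[1, ], R12[2, ])
    candidates[[1]] <- list(R = rbind(R12, r3), s = s)
  } else {
    n0 <- sv$v[, 3]
    # min-norm least squares: rows of A lie in the landmark plane
    d_inv <- ifelse(sv$d > 1e-9 * sv$d[1], 1 / sv$d, 0)
    pinv <- sv$v %*% diag(d_inv) %*% t(sv$u)
    A <- t(pinv %*% xc)
    m1 <- A[1, ]; m2 <- A[2, ]
    cc <- -sum(m1 * m2)
    dd <- sum(m2^2) - sum(m1^2)
    l1sq <- (dd + sqrt(dd^2 + 4 * cc^2)) / 2
    l1 <- sqrt(max(l1sq, 0))
    l2 <- if (l1 > 1e-12) cc / l1 else sqrt(max(-dd, 0))
    for (sgn in c(1, -1)) {
      r1 <- m1 + sgn * l1 * n0
      r2 <- m2 + sgn * l2 * n0
      s <- (vec_norm(r1) + vec_norm(r2)) / 2
      if (s <= 0) next
      R0 <- rbind(r1 / vec_norm(r1), r2 / vec_norm(r2))
      R0 <- rbind(R0, cross3(R0[1, ], R0[2, ]))
      candidates[[length(candidates) + 1]] <- list(R = nearest_rotation(R0), s = s)
    }
  }

  ambiguous <- FALSE
  pick <- 1L
  if (length(candidates) > 1) {
    if (!is.null(mesh)) {
      nrm <- face_normals(mesh)
      toward <- vapply(candidates, function(cd) {
        v <- cd$R[3, ]  # view direction into the scene
        mean(rowSums(nrm * rep(v, each = nrow(nrm))) < 0)
      }, numeric(1))
      if (diff(range(toward)) > 0.02) {
        pick <- which.max(toward)
      } else {
        # closed surfaces (e.g. a whole-sphere eye) split 50/50; fall back
        # to requiring the landmarks on the near side of the eye center
        nearside <- vapply(candidates, function(cd) {
          sum(cd$R[3, ] * colMeans(mesh$vertices)) - mean(X %*% cd$R[3, ])
        }, numeric(1))
        pick <- which.max(nearside)
      }
    } else {
      ambiguous <- TRUE
      # deterministic convention: non-negative out-of-plane lambda branch
      pick <- 1L
    }
  }
  cd <- candidates[[pick]]
  offset <- xbar - cd$s * (cd$R[1:2, , drop = FALSE] %*% Xbar)[, 1]
  pose <- camera_pose(cd$R, cd$s, offset)
  proj <- project_points(pose, X)
  resid <- sqrt(mean(rowSums((proj$px - x)^2)))
  pose$residual_px <- resid
  pose$flagged <- resid > flag_threshold_px
  attr(pose, "ambiguous") <- ambiguous
  pose
}

# Rasterize the whole mesh through a pose; returns depth/face-index buffers
# plus per-face projected centroid pixels, depths and front-facing flags.
rasterize_pose <- function(mesh, pose, image_size) {
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  pv <- project_points(pose, mesh$vertices)
  buf <- rasterize_mesh_cpp(pv$px, pv$depth, mesh$faces, w, h)
  pc <- project_points(pose, face_centroids(mesh))
  view <- pose$rotation[3, ]
  front <- rowSums(face_normals(mesh) * rep(view, each = nrow(mesh$faces))) < 0
  list(depth = buf$depth, face = buf$face, centroid_px = pc$px,
       centroid_depth = pc$depth, front = front,
       vertex_px = pv$px, vertex_depth = pv$depth, width = w, height = h)
}

# Median projected edge length (mm in depth units) used as the occlusion
# depth tolerance: one facet of slack.
median_edge_mm <- function(mesh) {
  cr <- face_corners(mesh)
  e <- c(sqrt(rowSums((cr$a - cr$b)^2)), sqrt(rowSums((cr$b - cr$c)^2)))
  stats::median(e)
}

#' Transfer a 2D annotation mask onto mesh faces
#'
#' Labels a face `DRA` iff it is front-facing, unoccluded (its centroid
#' passes a depth-buffer test at the pixel it projects to) and its centroid
#' projects into a `TRUE` mask pixel. Faces straddling the mask boundary are
#' decided by centroid membership; their total area is reported in the
#' `boundary_uncertainty_mm2` attribute.
#'
#' @param mesh a [surface_mesh()].
#' @param pose a [camera_pose()]; a flagged pose is refused unless
#'   `override = TRUE`.
#' @param mask logical matrix (rows = y, columns = x) in the same pixel
#'   frame as the landmarks used for the pose.
#' @param override proceed despite a flagged pose.
#' @param depth_tol_mm occlusion tolerance; default one median edge length.
#' @return the mesh with `DRA` face labels set.
#' @export
project_mask <- function(mesh, pose, mask, override = FALSE,
                         depth_tol_mm = NULL) {
  if (pose$flagged && !override)
    abort("pose is flagged (high reprojection residual); set override = TRUE to proceed")
  mask <- mask > 0
  if (is.null(depth_tol_mm)) depth_tol_mm <- 1.5 * median_edge_mm(mesh)
  rz <- rasterize_pose(mesh, pose, c(ncol(mask), nrow(mask)))
  cx <- round(rz$centroid_px[, 1]); cy <- round(rz$centroid_px[, 2])
  inside <- cx >= 1 & cx <= rz$width & cy >= 1 & cy <= rz$height
  lab <- rep(FALSE, nrow(mesh$faces))
  idx <- which(rz$front & inside)
  if (length(idx)) {
    pix <- cbind(cy[idx], cx[idx])
    zbuf <- rz$depth[pix]
    # grazing faces span a large depth range across one pixel; scale the
    # tolerance by the face slope so silhouette-rim faces are not dropped
    view <- pose$rotation[3, ]
    slope <- abs(rowSums(face_normals(mesh) * rep(view, each = nrow(mesh$faces))))
    tol <- depth_tol_mm / pmax(slope[idx], 0.05)
    visible <- rz$centroid_depth[idx] <= zbuf + tol
    in_mask <- mask[pix]
    lab[idx] <- visible & in_mask
  }
  out <- set_face_region(mesh, which(lab), "DRA")
  # boundary uncertainty: visible faces whose projected corners do not agree
  # with the centroid about mask membership
  vin <- function(px) {
    x <- round(px[, 1]); y <- round(px[, 2])
    ok <- x >= 1 & x <= rz$width & y >= 1 & y <= rz$height
    r <- rep(FALSE, nrow(px))
    r[ok] <- mask[cbind(y[ok], x[ok])]
    r
  }
  vmask <- cbind(vin(rz$vertex_px[mesh$faces[, 1], , drop = FALSE]),
                 vin(rz$vertex_px[mesh$faces[, 2], , drop = FALSE]),
                 vin(rz$vertex_px[mesh$faces[, 3], , drop = FALSE]))
  straddle <- rz$front & inside & (rowSums(vmask) %% 3 != 0)
  attr(out, "boundary_uncertainty_mm2") <- sum(face_areas(mesh)[straddle])
  out
}

#' Render a labeled region back into a 2D mask
#'
#' Depth-buffered rendering of the faces carrying `region`: a pixel is
#' `TRUE` iff the nearest face covering it belongs to the region (so far-side
#' copies of the region are occluded).
#'
#' @inheritParams project_mask
#' @param region region label to render.
#' @param image_size `(width, height)` in px.
#' @return logical matrix (rows = y, columns = x).
#' @export
reproject_region <- function(mesh, pose, region, image_size) {
  if (!(region %in% region_levels())) abort("unknown region label")
  ridx <- which(mesh$face_region == region)
  if (length(ridx) == 0) {
    warn(paste0("region '", region, "' has no faces; returning empty mask"))
    return(matrix(FALSE, image_size[2], image_size[1]))
  }
  rz <- rasterize_pose(mesh, pose, image_size)
  m <- matrix(FALSE, rz$height, rz$width)
  hit <- !is.na(rz$face)
  m[hit] <- rz$face[hit] %in% ridx
  m
}
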