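#' Parameters of a synthetic head/eye phantom
#'
#' The phantom eye is a sphere (so every area has a closed form): the DRA is
#' the spherical cap of angular radius `dra_angular_radius_rad` about
#' `dra_center_direction`, with analytic area \eqn{2\pi R^2(1-\cos\theta)}.
#' Three ocelli landmarks sit on the dorsal head around the cap. Layered
#' volume phantoms carry concentric lens / crystalline-cone / rhabdom shells
#' inward from the eye surface.
#'
#' @param eye_radius_mm eye radius (mm, > 0).
#' @param dra_center_direction unit 3-vector, center of the DRA cap.
#' @param dra_angular_radius_rad angular cap radius, in `[0, pi/2]`.
#' @param facet_pitch_mm center-to-center ommatidial spacing (mm).
#' @param ocelli_mm optional 3 x 3 matrix of ocelli positions (mm, rownames
#'   `ocellus_left/median/right`); placed automatically around the DRA when
#'   `NULL`.
#' @param layer_thicknesses_um named `(lens, cone, rhabdom)` thicknesses.
#' @param cone_width_um lateral crystalline-cone width (um).
#' @param aux_landmarks_mm optional extra named landmarks (rows) off the
#'   ocelli plane; by default one antenna-base point. Three ocelli alone are
#'   coplanar, which leaves the in-plane tilt sign of a scaled-orthographic
#'   pose fundamentally ambiguous (a reflection); one off-plane landmark,
#'   as is standard in landmark registration, removes the ambiguity.
#' @param seed integer seed for any stochastic decoration.
#' @export
phantom_params <- function(eye_radius_mm = 1.2,
                           dra_center_direction = c(0, 0, 1),
                           dra_angular_radius_rad = 0.3,
                           facet_pitch_mm = 0.025,
                           ocelli_mm = NULL,
                           layer_thicknesses_um = c(lens = 30, cone = 60, rhabdom = 90),
                           cone_width_um = 8,
                           aux_landmarks_mm = NULL,
                           seed = 1L) {
  if (!is.numeric(eye_radius_mm) || eye_radius_mm <= 0)
    abort("invalid phantom parameter 'eye_radius_mm': must be positive")
  if (length(dra_center_direction) != 3 || vec_norm(dra_center_direction) == 0)
    abort("invalid phantom parameter 'dra_center_direction': must be a nonzero 3-vector")
  if (dra_angular_radius_rad < 0 || dra_angular_radius_rad > pi / 2)
    abort("invalid phantom parameter 'dra_angular_radius_rad': must lie in [0, pi/2]")
  if (facet_pitch_mm <= 0)
    abort("invalid phantom parameter 'facet_pitch_mm': must be positive")
  lt <- layer_thicknesses_um
  if (length(lt) != 3 || any(lt <= 0))
    abort("invalid phantom parameter 'layer_thicknesses_um': need 3 positive values")
  if (is.null(names(lt))) names(lt) <- c("lens", "cone", "rhabdom")
  if (cone_width_um <= 0)
    abort("invalid phantom parameter 'cone_width_um': must be positive")
  u <- normalize(dra_center_direction)
  if (is.null(ocelli_mm)) {
    b <- orthobasis(u)
    ang <- c(0.45, 0.55, 0.50)
    az <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
    ocelli_mm <- t(vapply(1:3, function(i) {
      1.02 * eye_radius_mm *
        (sin(ang[i]) * (cos(az[i]) * b$e1 + sin(az[i]) * b$e2) + cos(ang[i]) * u)
    }, numeric(3)))
    rownames(ocelli_mm) <- c("ocellus_left", "ocellus_median", "ocellus_right")
  }
  ocelli_mm <- as.matrix(ocelli_mm)
  if (!all(dim(ocelli_mm) == c(3, 3))) abort("invalid phantom parameter 'ocelli_mm': need 3 x 3")
  tri <- vec_norm(cross3(ocelli_mm[2, ] - ocelli_mm[1, ],
                         ocelli_mm[3, ] - ocelli_mm[1, ])) / 2
  if (tri <= 1e-12)
    abort("invalid phantom parameter 'ocelli_mm': ocelli are collinear")
  if (is.null(aux_landmarks_mm)) {
    b <- orthobasis(u)
    ang <- 1.15
    aux_landmarks_mm <- matrix(
      1.02 * eye_radius_mm *
        (sin(ang) * (cos(-pi / 2) * b$e1 + sin(-pi / 2) * b$e2) + cos(ang) * u),
      nrow = 1, dimnames = list("antenna_base_left", NULL))
  }
  structure(
    list(eye_radius_mm = eye_radius_mm, dra_center_direction = u,
         dra_angular_radius_rad = dra_angular_radius_rad,
         facet_pitch_mm = facet_pitch_mm, ocelli_mm = ocelli_mm,
         aux_landmarks_mm = as.matrix(aux_landmarks_mm),
         layer_thicknesses_um = lt, cone_width_um = cone_width_um,
         seed = as.integer(seed)),
    class = "phantom_params"
  )
}

# All named registration landmarks of a phantom (ocelli + auxiliary).
phantom_landmarks_mm <- function(params) {
  rbind(params$ocelli_mm, params$aux_landmarks_mm)
}

#' Analytic spherical-cap area
#' @param radius_mm sphere radius (mm).
#' @param theta_rad angular cap radius.
#' @return cap area `2 pi R^2 (1 - cos theta)` in mm^2.
#' @export
spherical_cap_area <- function(radius_mm, theta_rad) {
  2 * pi * radius_mm^2 * (1 - cos(theta_rad))
}

#' Build a head phantom with known ground truth
#'
#' Generates a watertight icosphere eye of the stated refinement, labels the
#' faces whose centroid lies within the DRA cap, records the analytic truth
#' areas, and renders the reference view (exact DRA mask + projected ocelli)
#' through a default pose looking at the DRA.
#'
#' @param params a [phantom_params()].
#' @param subdivisions icosphere refinement; 5 gives 20480 faces.
#' @param image_size rendered view size `(width, height)` px.
#' @param tilt_rad tilt of the default view away from the cap axis.
#' @return an object of class `phantom_truth`: fields `params`, `mesh` (true
#'   DRA labels), `true_dra_area_mm2`, `true_eye_area_mm2`, `pose`,
#'   `rendered_mask`, `raster`, `landmark_px`, `layer_thicknesses_um`,
#'   `cone_width_um`.
#' @export
make_head_phantom <- function(params = phantom_params(), subdivisions = 5L,
                              image_size = c(480, 480), tilt_rad = 0) {
  stopifnot(inherits(params, "phantom_params"))
  ico <- icosphere(subdivisions)
  mesh <- surface_mesh(ico$vertices * params$eye_radius_mm, ico$faces)
  mesh <- orient_outward(mesh, c(0, 0, 0))
  cen <- face_centroids(mesh)
  cosang <- (cen %*% params$dra_center_direction) /
    sqrt(rowSums(cen^2))
  dra_faces <- which(acos(clamp(cosang, -1, 1)) <= params$dra_angular_radius_rad)
  mesh <- set_face_region(mesh, dra_faces, "DRA")
  scale <- 0.40 * min(image_size) / params$eye_radius_mm
  pose <- pose_toward(params$dra_center_direction, scale, image_size,
                      tilt_rad = tilt_rad)
  truth <- structure(
    list(params = params, mesh = mesh,
         true_dra_area_mm2 = spherical_cap_area(params$eye_radius_mm,
                                                params$dra_angular_radius_rad),
         true_eye_area_mm2 = 4 * pi * params$eye_radius_mm^2,
         pose = pose, rendered_mask = NULL, raster = NULL, landmark_px = NULL,
         layer_thicknesses_um = params$layer_thicknesses_um,
         cone_width_um = params$cone_width_um),
    class = "phantom_truth"
  )
  rv <- render_view(truth, pose, image_size)
  truth$rendered_mask <- rv$mask
  truth$raster <- rv$raster
  truth$landmark_px <- rv$landmark_px
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> R =", x$params$eye_radius_mm, "mm, theta =",
      x$params$dra_angular_radius_rad, "rad\n")
  cat("  true DRA area:", format(x$true_dra_area_mm2, digits = 6),
      "mm^2 of", format(x$true_eye_area_mm2, digits = 6), "mm^2 eye\n")
  invisible(x)
}

#' Render an orthographic view of a phantom
#'
#' Depth-buffered rendering: the mask contains exactly the pixels whose
#' nearest surface face is a true-DRA face (front-facing and unoccluded by
#' construction of the depth buffer); the raster is a simple Lambert-shaded
#' grayscale view in `[0, 1]` with the DRA patch rendered lighter, matching
#' its appearance in photographs; landmarks are the projected ocelli.
#'
#' @param truth a `phantom_truth` (or any list with `mesh` and
#'   `params$ocelli_mm`).
#' @param pose a [camera_pose()].
#' @param image_size `(width, height)` px.
#' @return list with `raster` (numeric matrix), `mask` (logical matrix) and
#'   `landmark_px` (3 x 2 named matrix).
#' @export
render_view <- function(truth, pose, image_size) {
  mesh <- truth$mesh
  if (any(image_size < 1)) abort("image_size must be positive")
  rz <- rasterize_pose(mesh, pose, image_size)
  if (all(is.na(rz$face)))
    abort("render error: eye projects entirely outside the frame")
  dra_faces <- which(mesh$face_region == "DRA")
  hit <- !is.na(rz$face)
  mask <- matrix(FALSE, rz$height, rz$width)
  mask[hit] <- rz$face[hit] %in% dra_faces
  # Lambert shading against the viewing direction
  nrm <- face_normals(mesh)
  lam <- pmax(0, -(nrm %*% pose$rotation[3, ]))
  base <- ifelse(seq_len(nrow(nrm)) %in% dra_faces, 0.55, 0.25)
  gain <- ifelse(seq_len(nrow(nrm)) %in% dra_faces, 0.40, 0.50)
  shade <- base + gain * lam
  raster <- matrix(0.08, rz$height, rz$width)
  raster[hit] <- shade[rz$face[hit]]
  lmm <- phantom_landmarks_mm(truth$params)
  lm <- project_points(pose, lmm)
  landmark_px <- lm$px
  rownames(landmark_px) <- rownames(lmm)
  list(raster = raster, mask = mask, landmark_px = landmark_px)
}

#' Emulate a manual annotation of a binary mask
#'
#' Perturbs the boundary of a (star-shaped) mask with a smooth random radial
#' field, emulating the boundary placement error of a human tracing the grey
#' DRA region in an image editor. The perturbation is a periodic Gaussian
#' process over the boundary angle (harmonics 0..`n_harmonics`, total
#' standard deviation `sd_px`).
#'
#' @param mask logical matrix (rows = y, columns = x).
#' @param sd_px boundary placement error (pixels).
#' @param n_harmonics number of nonconstant harmonics.
#' @param seed RNG seed.
#' @return a logical matrix of the same size.
#' @export
annotate_mask <- function(mask, sd_px = 2, n_harmonics = 3, seed = 1L) {
  mask <- mask > 0
  if (!any(mask)) return(mask)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  nb <- 256L
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)
  rr <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  bin <- pmin(nb, 1L + floor((ang + pi) / (2 * pi) * nb))
  b <- rep(NA_real_, nb)
  agg <- tapply(rr, bin, max)
  b[as.integer(names(agg))] <- agg
  # fill empty bins by nearest filled bin (circular), then smooth lightly
  if (anyNA(b)) {
    filled <- which(!is.na(b))
    for (i in which(is.na(b))) {
      d <- pmin(abs(filled - i), nb - abs(filled - i))
      b[i] <- b[filled[which.min(d)]]
    }
  }
  ker <- rep(1 / 5, 5)
  bpad <- c(b[(nb - 1):nb], b, b[1:2])
  b <- vapply(seq_len(nb), function(i) sum(bpad[i:(i + 4)] * ker), numeric(1))
  co <- with_seed(seed, rnorm(2 * n_harmonics + 1, 0,
                              sd_px / sqrt(1 + n_harmonics)))
  th <- (seq_len(nb) - 0.5) / nb * 2 * pi - pi
  eta <- rep(co[1], nb)
  for (k in seq_len(n_harmonics)) {
    eta <- eta + co[2 * k] * cos(k * th) + co[2 * k + 1] * sin(k * th)
  }
  # evaluate every pixel in a bounding box around the perturbed boundary
  rmax <- max(b + eta) + 2
  rows <- max(1, floor(cy - rmax)):min(nrow(mask), ceiling(cy + rmax))
  cols <- max(1, floor(cx - rmax)):min(ncol(mask), ceiling(cx + rmax))
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  pr <- sqrt((py - cy)^2 + (px - cx)^2)
  pth <- atan2(py - cy, px - cx)
  pbin <- pmin(nb, 1L + floor((pth + pi) / (2 * pi) * nb))
  keep <- pr <= (b + eta)[pbin]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[cbind(py[keep], px[keep])] <- TRUE
  out
}

#' Build a layered volume phantom with known truth
#'
#' Emulates a reconstructed micro-CT volume of the phantom eye: concentric
#' shells inward from the sphere surface carry distinct gray levels for the
#' lens, the crystalline-cone layer (with a periodic banding of lateral
#' width `cone_width_um` along the polar direction) and the rhabdom layer.
#' The crystalline-cone layer inside the DRA cap can be built thinner
#' (`dra_cone_scale`) to emulate the region contrast seen in bumblebees, and
#' an optional gap can be cut into the rhabdom shell for continuity-QC
#' testing. Gray levels are fixed documented constants plus optional
#' Gaussian noise.
#'
#' @param params a [phantom_params()]; note that volume phantoms are
#'   typically built miniaturized (eye radius around 0.2 mm) so whole
#'   volumes at micro-CT voxel size stay small.
#' @param voxel_size_um isotropic voxel size, default 1.625.
#' @param noise_sd_frac Gaussian gray noise as a fraction of the 16-bit
#'   dynamic range (default 0.02).
#' @param dra_cone_scale multiplier on cone thickness inside the DRA.
#' @param rhabdom_gap_um arc length of a gap cut into the rhabdom shell
#'   (0 = none) at polar angle `rhabdom_gap_at_rad`.
#' @param rhabdom_gap_at_rad polar angle of the gap center.
#' @param margin_um background margin around the eye.
#' @param seed RNG seed for the gray noise.
#' @return list with `volume` (gray [volume_image()]), `label` (binary eye
#'   label volume) and `truth` (gray levels, shell radii per region, layer
#'   thicknesses, cap geometry).
#' @export
make_volume_phantom <- function(params, voxel_size_um = 1.625,
                                noise_sd_frac = 0.02, dra_cone_scale = 1,
                                rhabdom_gap_um = 0,
                                rhabdom_gap_at_rad = pi / 3,
                                margin_um = 4 * voxel_size_um, seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  if (voxel_size_um <= 0) abort("voxel_size_um must be positive")
  lt <- params$layer_thicknesses_um
  t_cone_min <- lt[["cone"]] * min(1, dra_cone_scale)
  if (min(lt[["lens"]], t_cone_min, lt[["rhabdom"]]) < 3 * voxel_size_um)
    abort(paste0("resolution error: a layer spans fewer than 3 voxels at ",
                 voxel_size_um, " um"))
  R_um <- params$eye_radius_mm * 1000
  half <- as.integer(ceiling((R_um + margin_um) / voxel_size_um))
  n <- 2L * half + 1L
  c0 <- half + 1
  xs <- (seq_len(n) - c0) * voxel_size_um
  x2 <- xs^2
  r <- sqrt(outer(outer(x2, x2, "+"), x2, "+"))
  u <- params$dra_center_direction
  dotv <- outer(outer(xs * u[1], xs * u[2], "+"), xs * u[3], "+")
  angv <- acos(clamp(ifelse(r > 0, dotv / pmax(r, 1e-9), 1), -1, 1))
  rm(dotv)

  gl <- c(background = 5000, lens = 30000, cone_hi = 22000, cone_lo = 18000,
          rhabdom = 45000, interior = 12000)
  theta <- params$dra_angular_radius_rad
  in_dra <- angv <= theta
  R1 <- R_um
  R2 <- R1 - lt[["lens"]]
  t_cone <- ifelse(in_dra, lt[["cone"]] * dra_cone_scale, lt[["cone"]])
  R3 <- R2 - t_cone
  R4 <- R3 - lt[["rhabdom"]]

  gray <- array(gl[["background"]], dim = c(n, n, n))
  gray[r <= R1] <- gl[["lens"]]
  in_cone <- r <= R2 & r > R3
  # banding period is the cone width at the cone layer's own mid radius
  R_cone_mid <- R2 - lt[["cone"]] / 2
  band <- (floor((angv * R_cone_mid) / params$cone_width_um) %% 2) == 0
  gray[in_cone & band] <- gl[["cone_hi"]]
  gray[in_cone & !band] <- gl[["cone_lo"]]
  in_rhab <- r <= R3 & r > R4
  gray[in_rhab] <- gl[["rhabdom"]]
  if (rhabdom_gap_um > 0) {
    R_rh_mid <- mean(c(R2 - lt[["cone"]], R2 - lt[["cone"]] - lt[["rhabdom"]]))
    half_ang <- rhabdom_gap_um / (2 * R_rh_mid)
    gap <- in_rhab & abs(angv - rhabdom_gap_at_rad) <= half_ang
    gray[gap] <- gl[["interior"]]
  }
  gray[r <= R4] <- gl[["interior"]]
  rm(in_cone, in_rhab, band, angv)

  if (noise_sd_frac > 0) {
    gray <- with_seed(seed, {
      gray + array(rnorm(length(gray), 0, noise_sd_frac * 65535), dim = dim(gray))
    })
    gray <- clamp(gray, 0, 65535)
  }
  origin <- rep(-(c0 - 1) * voxel_size_um / 1000, 3)
  vol <- volume_image(gray, voxel_size_um, origin)
  lab <- volume_image(array(as.numeric(r <= R1), dim = c(n, n, n)),
                      voxel_size_um, origin)
  truth <- list(
    gray_levels = gl,
    radii_um = list(
      non_DRA = c(outer = R1, lens_cone = R2, cone_rhabdom = R2 - lt[["cone"]],
                  rhabdom_interior = R2 - lt[["cone"]] - lt[["rhabdom"]]),
      DRA = c(outer = R1, lens_cone = R2,
              cone_rhabdom = R2 - lt[["cone"]] * dra_cone_scale,
              rhabdom_interior = R2 - lt[["cone"]] * dra_cone_scale - lt[["rhabdom"]])
    ),
    layer_thicknesses_um = lt,
    dra_cone_scale = dra_cone_scale,
    cone_width_um = params$cone_width_um,
    dra_angular_radius_rad = theta,
    eye_radius_um = R_um,
    center_mm = c(0, 0, 0),
    rhabdom_gap_um = rhabdom_gap_um,
    rhabdom_gap_at_rad = rhabdom_gap_at_rad
  )
  list(volume = vol, label = lab, truth = truth)
}

#' Generate an allometric cohort with a known power law
#'
#' Rows follow `log(sqrt(area)) = intercept + slope * log(ITD) + e`,
#' `e ~ Normal(0, noise_sd)`, with ITD drawn uniformly from `itd_range_mm`.
#' Whole-eye areas follow the same law with their own intercept/noise.
#'
#' @param n cohort size (>= 3).
#' @param slope,intercept power-law parameters for the DRA on the
#'   log(sqrt-area) scale.
#' @param noise_sd residual SD on the log scale (>= 0).
#' @param itd_range_mm inter-tegular distance range (mm).
#' @param seed RNG seed; generation is reproducible for a fixed seed.
#' @param eye_slope,eye_intercept,eye_noise_sd same-law parameters for the
#'   whole compound eye.
#' @return tibble with `specimen_id`, `itd_mm`, `dra_area_mm2`,
#'   `eye_area_mm2`.
#' @export
make_allometric_cohort <- function(n = 20, slope = 0.8, intercept = -1.7,
                                   noise_sd = 0.05,
                                   itd_range_mm = c(2.965, 5.776), seed = 1L,
                                   eye_slope = slope, eye_intercept = -0.4,
                                   eye_noise_sd = noise_sd) {
  if (n < 3) abort("n must be at least 3")
  if (noise_sd < 0 || eye_noise_sd < 0) abort("noise_sd must be nonnegative")
  if (any(itd_range_mm <= 0) || itd_range_mm[1] > itd_range_mm[2])
    abort("itd_range_mm must be a positive increasing range")
  with_seed(seed, {
    itd <- sort(runif(n, itd_range_mm[1], itd_range_mm[2]))
    lin_dra <- intercept + slope * log(itd) + rnorm(n, 0, noise_sd)
    lin_eye <- eye_intercept + eye_slope * log(itd) + rnorm(n, 0, eye_noise_sd)
    tibble(
      specimen_id = sprintf("s%02d", seq_len(n)),
      itd_mm = itd,
      dra_area_mm2 = exp(2 * lin_dra),
      eye_area_mm2 = exp(2 * lin_eye)
    )
  })
}

#' Simulate an ommatidial measurement table
#'
#' Draws structure measurements for a cohort of specimens with given true
#' region means, a specimen-level random effect and measurement noise —
#' the lightweight counterpart of running the virtual-histology pipeline,
#' used for calibration studies (e.g. type-I error of the region
#' comparison under identical regions).
#'
#' @param n_specimens number of eyes.
#' @param region_means_um named vector of true means (names from
#'   `DRA`, `proximate`, `non_DRA`).
#' @param n_per_region measurements per specimen and region.
#' @param specimen_sd_um between-specimen SD.
#' @param measurement_sd_um within-specimen measurement SD.
#' @param structure,dimension vocabulary tags for the output table.
#' @param seed RNG seed.
#' @return tidy tibble (`specimen_id`, `slice_id`, `region`, `structure`,
#'   `dimension`, `value_um`).
#' @export
simulate_ommatidial_measurements <- function(n_specimens = 6,
                                             region_means_um = c(DRA = 60, proximate = 60, non_DRA = 60),
                                             n_per_region = 7,
                                             specimen_sd_um = 1.5,
                                             measurement_sd_um = 1.0,
                                             structure = "cone",
                                             dimension = "thickness",
                                             seed = 1L) {
  regions <- names(region_means_um)
  with_seed(seed, {
    spec_eff <- rnorm(n_specimens, 0, specimen_sd_um)
    rows <- lapply(seq_len(n_specimens), function(s) {
      lapply(regions, function(rg) {
        tibble(
          specimen_id = sprintf("s%02d", s),
          slice_id = sprintf("slice%02d", seq_len(n_per_region)),
          region = rg, structure = structure, dimension = dimension,
          value_um = region_means_um[[rg]] + spec_eff[s] +
            rnorm(n_per_region, 0, measurement_sd_um)
        )
      })
    })
    dplyr::bind_rows(rows)
  })
}

#' Measure ommatidial structures on a cohort of volume phantoms
#'
#' Builds `n_specimens` layered volume phantoms (optionally with a thinner
#' crystalline-cone layer inside the DRA) and measures lens, cone and
#' rhabdom thickness along radial profiles in each of the three eye
#' regions, with region membership taken from the phantom's ground-truth
#' cap geometry (DRA within the cap; proximate within `proximate_rows`
#' facet pitches of the cap edge; non-DRA beyond `non_dra_rows`). This is
#' the volumetric counterpart of the measurement stage of the full
#' pipeline, at a scale suited to repeated simulation.
#'
#' @param n_specimens number of phantom eyes.
#' @param dra_cone_scale DRA cone-thickness multiplier (1 = null phantom).
#' @param eye_radius_mm phantom eye radius.
#' @param profiles_per_region radial profiles per region and specimen.
#' @param proximate_rows,non_dra_rows region band definition (rows of
#'   facet pitch).
#' @param noise_sd_frac volume gray noise.
#' @param seed master seed.
#' @return tidy measurement tibble as in
#'   [simulate_ommatidial_measurements()].
#' @export
phantom_measurement_cohort <- function(n_specimens = 6, dra_cone_scale = 0.8,
                                       eye_radius_mm = 0.16,
                                       profiles_per_region = 2L,
                                       proximate_rows = 5L, non_dra_rows = 20L,
                                       noise_sd_frac = 0.02, seed = 1L) {
  seeds <- child_seeds(seed, 2L * n_specimens)
  lt <- c(lens = 18, cone = 36, rhabdom = 50)
  pitch_mm <- 0.008
  theta <- 0.25
  R_um <- eye_radius_mm * 1000
  ang_prox_hi <- theta + proximate_rows * pitch_mm * 1000 / R_um
  ang_non_lo <- theta + non_dra_rows * pitch_mm * 1000 / R_um
  if (ang_non_lo >= pi)
    abort("eye too small for the requested non-DRA band")
  rows <- list()
  for (s in seq_len(n_specimens)) {
    params <- phantom_params(eye_radius_mm = eye_radius_mm,
                             dra_angular_radius_rad = theta,
                             facet_pitch_mm = pitch_mm,
                             layer_thicknesses_um = lt, cone_width_um = 8,
                             seed = seeds[2 * s - 1])
    vp <- make_volume_phantom(params, dra_cone_scale = dra_cone_scale,
                              noise_sd_frac = noise_sd_frac,
                              seed = seeds[2 * s - 1])
    ang_ranges <- list(DRA = c(0, theta * 0.9),
                       proximate = c(theta * 1.05, ang_prox_hi),
                       non_DRA = c(ang_non_lo, min(pi - 0.1, ang_non_lo + 0.6)))
    dirs <- with_seed(seeds[2 * s], {
      do.call(rbind, lapply(names(ang_ranges), function(rg) {
        rr <- ang_ranges[[rg]]
        ang <- acos(runif(profiles_per_region, cos(rr[2]), cos(rr[1])))
        az <- runif(profiles_per_region, 0, 2 * pi)
        cbind(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang))
      }))
    })
    regs <- rep(names(ang_ranges), each = profiles_per_region)
    spacing <- vp$volume$voxel_size_um / 2
    for (k in seq_len(nrow(dirs))) {
      d <- normalize(dirs[k, ])
      start <- d * (R_um + 12 * vp$volume$voxel_size_um) / 1000
      prof <- extract_profile(vp$volume, start, -d,
                              sum(lt) + 30 * vp$volume$voxel_size_um, spacing)
      meas <- tryCatch(
        measure_layer(prof, spacing, dynamic_range = 65535),
        error = function(e) NULL)
      if (is.null(meas) || length(meas$boundaries_um) < 4) next
      rows[[length(rows) + 1]] <- tibble(
        specimen_id = sprintf("s%02d", s),
        slice_id = sprintf("profile%02d", k),
        region = regs[k],
        structure = c("lens", "cone", "rhabdom"),
        dimension = "thickness",
        value_um = diff(meas$boundaries_um[1:4])
      )
    }
  }
  dplyr::bind_rows(rows)
}
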