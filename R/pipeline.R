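# Project-level orchestration: synthetic fixture projects on disk, the
# end-to-end per-specimen pipeline, and the study-level phantom cohorts
# used for method validation.

#' Default pipeline configuration
#'
#' Flat, documented configuration for [run_pipeline()] /
#' [make_fixtures()]. Units: mm for lengths and mesh coordinates, mm^2 for
#' areas, um for ommatidial structures and voxel size.
#'
#' @param grid_pitch_mm pitch of the calibration grid glued to the head.
#' @param thorax_grid_pitch_mm pitch of the thorax-photo calibration grid.
#' @param facet_pitch_mm ommatidial center-to-center spacing, used to
#'   convert "ommatidial rows" into geodesic distances.
#' @param proximate_rows,non_dra_rows region band definition (rows).
#' @param n_slices virtual slices per eye (default 7).
#' @param rhabdom_band gray range identifying rhabdom pixels for QC.
#' @param gap_tolerance_um rhabdom-continuity gap tolerance; default twice
#'   the voxel size at acquisition.
#' @param profiles_per_region radial thickness profiles per region.
#' @param width_regions regions in which a lateral cone-width profile is
#'   taken; the default allocation yields 20 structure measurements per
#'   specimen (2 profiles x 3 layers x 3 regions + 2 widths).
#' @param flag_threshold_px pose residual above which a pose is flagged.
#' @param min_contrast boundary-detection contrast guard (fraction of the
#'   16-bit dynamic range).
#' @param seed master seed for the run.
#' @export
pipeline_config <- function(grid_pitch_mm = 0.02,
                            thorax_grid_pitch_mm = 1,
                            facet_pitch_mm = 0.008,
                            proximate_rows = 5L, non_dra_rows = 20L,
                            n_slices = 7L,
                            rhabdom_band = c(38000, 52000),
                            gap_tolerance_um = 2 * 1.625,
                            profiles_per_region = 2L,
                            width_regions = c("DRA", "non_DRA"),
                            flag_threshold_px = 5,
                            min_contrast = 0.10,
                            seed = 1L) {
  cfg <- list(grid_pitch_mm = grid_pitch_mm,
              thorax_grid_pitch_mm = thorax_grid_pitch_mm,
              facet_pitch_mm = facet_pitch_mm,
              proximate_rows = proximate_rows, non_dra_rows = non_dra_rows,
              n_slices = n_slices, rhabdom_band = rhabdom_band,
              gap_tolerance_um = gap_tolerance_um,
              profiles_per_region = profiles_per_region,
              width_regions = width_regions,
              flag_threshold_px = flag_threshold_px,
              min_contrast = min_contrast, seed = as.integer(seed))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(cond, what) {
    if (!cond) abort(paste0("config error: ", what))
  }
  chk(is.list(cfg), "config must be a list")
  pos <- c("grid_pitch_mm", "thorax_grid_pitch_mm", "facet_pitch_mm",
           "gap_tolerance_um", "flag_threshold_px", "min_contrast")
  for (k in pos) chk(is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1 && cfg[[k]] > 0,
                     paste(k, "must be a positive scalar"))
  chk(is.numeric(cfg$n_slices) && cfg$n_slices >= 1, "n_slices must be >= 1")
  chk(is.numeric(cfg$profiles_per_region) && cfg$profiles_per_region >= 1,
      "profiles_per_region must be >= 1")
  chk(length(cfg$rhabdom_band) == 2 && cfg$rhabdom_band[1] < cfg$rhabdom_band[2],
      "rhabdom_band must be an increasing range")
  chk(cfg$proximate_rows > 0 && cfg$proximate_rows < cfg$non_dra_rows,
      "need 0 < proximate_rows < non_dra_rows")
  chk(all(cfg$width_regions %in% c("DRA", "proximate", "non_DRA")),
      "width_regions must be DRA/proximate/non_DRA")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be an integer")
  invisible(cfg)
}

# Phantom study conditions shared by fixtures: a miniaturized eye (so whole
# micro-CT volumes at 1.625 um stay desk-sized) whose every layer still
# spans >= 10 voxels.
fixture_phantom_params <- function(itd_mm, theta = 0.25, seed = 1L) {
  phantom_params(
    eye_radius_mm = 0.04 * itd_mm,
    dra_center_direction = c(0, 0, 1),
    dra_angular_radius_rad = theta,
    facet_pitch_mm = 0.008,
    layer_thicknesses_um = c(lens = 18, cone = 36, rhabdom = 50),
    cone_width_um = 8,
    seed = seed
  )
}

# Ocelli pulled close to the DRA so they stay inside a close-up frame.
closeup_ocelli <- function(eye_radius_mm, u, theta) {
  b <- orthobasis(u)
  ang <- theta + c(0.10, 0.16, 0.13)
  az <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  oc <- t(vapply(1:3, function(i) {
    1.02 * eye_radius_mm *
      (sin(ang[i]) * (cos(az[i]) * b$e1 + sin(az[i]) * b$e2) + cos(ang[i]) * u)
  }, numeric(3)))
  rownames(oc) <- c("ocellus_left", "ocellus_median", "ocellus_right")
  oc
}

# Synthetic clicked grid corners for a grid of the given pitch seen at
# scale_px_per_mm, with small click noise.
synthetic_grid_points <- function(scale_px_per_mm, pitch_mm, origin_px = c(40, 40),
                                  n = 3L, click_sd_px = 0.2, seed = 1L) {
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  with_seed(seed, {
    data.frame(
      i = ij$i, j = ij$j,
      x_px = origin_px[1] + ij$i * pitch_mm * scale_px_per_mm + rnorm(nrow(ij), 0, click_sd_px),
      y_px = origin_px[2] + ij$j * pitch_mm * scale_px_per_mm + rnorm(nrow(ij), 0, click_sd_px)
    )
  })
}

#' Write a complete synthetic project to disk
#'
#' Emits a phantom project ready for [run_pipeline()]: by default six
#' specimens, two from each body-size class, each with a close-up DRA
#' "photograph" + two independently jittered manual annotations (one used
#' for 2D planimetry, one guiding the 3D segmentation), ocelli landmarks in
#' both frames, calibration grid points, a reconstructed gray volume and a
#' binary eye-label volume, plus a manifest CSV and a config JSON.
#'
#' @param dir output directory (created if needed).
#' @param n_per_class specimens per size class (small/medium/large).
#' @param seed master seed; two runs with the same seed produce identical
#'   projects.
#' @param config a [pipeline_config()].
#' @param annotation_sd_px manual-annotation boundary jitter.
#' @param dra_cone_scale DRA cone-layer thickness multiplier built into the
#'   volumes (the bumblebee-like contrast; 1 = null phantom).
#' @param voxel_size_um reconstruction voxel size.
#' @param image_size photo size in px.
#' @return invisibly, the manifest path.
#' @export
make_fixtures <- function(dir, n_per_class = 2L, seed = 1L,
                          config = pipeline_config(seed = seed),
                          annotation_sd_px = 2,
                          dra_cone_scale = 0.8,
                          voxel_size_um = 1.625,
                          image_size = c(360, 360)) {
  validate_config(config)
  if (n_per_class < 1) abort("config error: n_per_class must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) abort(paste("cannot write to", dir))
  classes <- c("small", "medium", "large")
  bounds <- size_class_bounds()
  n <- 3L * n_per_class
  seeds <- child_seeds(seed, n * 8L + 1L)
  itd <- with_seed(seeds[n * 8L + 1L], {
    unlist(lapply(1:3, function(k) {
      runif(n_per_class, bounds[k] + 0.1, bounds[k + 1] - 0.1)
    }))
  })
  rows <- list()
  for (s in seq_len(n)) {
    sid <- sprintf("s%02d", s)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    sd_base <- (s - 1L) * 8L
    theta <- 0.25
    params <- fixture_phantom_params(itd[s], theta = theta, seed = seeds[sd_base + 1])
    params$ocelli_mm <- closeup_ocelli(params$eye_radius_mm,
                                       params$dra_center_direction, theta)
    # close-up view: the DRA fills ~40% of the frame
    scale <- 0.21 * min(image_size) / (params$eye_radius_mm * sin(theta))
    pose <- pose_toward(params$dra_center_direction, scale, image_size,
                        tilt_rad = 0.10)
    truth <- make_head_phantom(params, subdivisions = 5L,
                               image_size = image_size)
    rv <- render_view(truth, pose, image_size)
    mask2d <- annotate_mask(rv$mask, sd_px = annotation_sd_px,
                            seed = seeds[sd_base + 2])
    mask3d <- annotate_mask(rv$mask, sd_px = annotation_sd_px,
                            seed = seeds[sd_base + 3])
    write_image_png(rv$raster, file.path(sdir, "photo.png"))
    write_image_png(rv$mask, file.path(sdir, "mask_exact.png"))
    write_image_png(mask2d, file.path(sdir, "mask_2d.png"))
    write_image_png(mask3d, file.path(sdir, "mask_3d.png"))
    # landmarks: ocelli in both frames, grid corners, tegula points
    nlm <- nrow(rv$landmark_px)
    lm2 <- rv$landmark_px + with_seed(seeds[sd_base + 4],
                                      matrix(rnorm(2 * nlm, 0, 0.3), nlm, 2))
    rownames(lm2) <- rownames(rv$landmark_px)
    grid_pts <- synthetic_grid_points(scale, config$grid_pitch_mm,
                                      seed = seeds[sd_base + 5])
    thorax_scale <- 100  # px per mm in the thorax photo
    tg <- synthetic_grid_points(thorax_scale, config$thorax_grid_pitch_mm,
                                seed = seeds[sd_base + 6])
    tegula <- list(tegula_left = c(100, 120),
                   tegula_right = c(100 + itd[s] * thorax_scale, 120))
    write_landmarks_json(
      file.path(sdir, "landmarks.json"),
      points_2d_px = lm2, points_3d_mm = phantom_landmarks_mm(params),
      extra = list(grid_points = grid_pts, thorax_grid_points = tg,
                   tegula_left_px = tegula$tegula_left,
                   tegula_right_px = tegula$tegula_right))
    vp <- make_volume_phantom(params, voxel_size_um = voxel_size_um,
                              dra_cone_scale = dra_cone_scale,
                              seed = seeds[sd_base + 7])
    write_volume_tiff(vp$volume, file.path(sdir, "volume.tif"))
    write_volume_tiff(vp$label, file.path(sdir, "label.tif"))
    jsonlite::write_json(
      list(itd_mm = itd[s], theta = theta,
           eye_radius_mm = params$eye_radius_mm,
           true_dra_area_mm2 = truth$true_dra_area_mm2,
           true_eye_area_mm2 = truth$true_eye_area_mm2,
           layer_thicknesses_um = as.list(params$layer_thicknesses_um),
           dra_cone_scale = dra_cone_scale,
           cone_width_um = params$cone_width_um),
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    rows[[s]] <- tibble(
      specimen_id = sid,
      photo = file.path(sdir, "photo.png"),
      mask_2d = file.path(sdir, "mask_2d.png"),
      mask_3d = file.path(sdir, "mask_3d.png"),
      landmarks = file.path(sdir, "landmarks.json"),
      volume = file.path(sdir, "volume.tif"),
      label = file.path(sdir, "label.tif"),
      truth = file.path(sdir, "truth.json")
    )
  }
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

# Radial thickness profiles + lateral cone-width profiles for a set of
# directions with known region labels; shared by run_pipeline() and the
# phantom validation studies.
measure_structures <- function(volume, center_mm, directions, regions,
                               outer_radius_um, depth_um,
                               dra_axis = c(0, 0, 1),
                               min_contrast = 0.10,
                               specimen_id = "s01",
                               width_directions = NULL,
                               width_regions = NULL,
                               width_r_mid_um = NULL,
                               cone_width_hint_um = 8) {
  rows <- list()
  spacing <- volume$voxel_size_um / 2
  for (k in seq_len(nrow(directions))) {
    d <- normalize(directions[k, ])
    start <- center_mm + d * (outer_radius_um + 12 * volume$voxel_size_um) / 1000
    prof <- extract_profile(volume, start, -d, depth_um, spacing)
    meas <- tryCatch(
      measure_layer(prof, spacing, min_contrast = min_contrast,
                    dynamic_range = 65535),
      error = function(e) NULL)
    if (is.null(meas) || length(meas$boundaries_um) < 4) next
    th <- diff(meas$boundaries_um[1:4])
    rows[[length(rows) + 1]] <- tibble(
      specimen_id = specimen_id,
      slice_id = sprintf("profile%02d", k),
      region = regions[k],
      structure = c("lens", "cone", "rhabdom"),
      dimension = "thickness",
      value_um = th
    )
  }
  if (!is.null(width_directions)) {
    for (k in seq_len(nrow(width_directions))) {
      d <- normalize(width_directions[k, ])
      # arc through the cone layer, along the polar (banding) direction
      tangent <- dra_axis - sum(dra_axis * d) * d
      if (vec_norm(tangent) < 1e-6) tangent <- orthobasis(d)$e1
      tangent <- normalize(tangent)
      axis <- normalize(cross3(d, tangent))
      r_mid_mm <- width_r_mid_um / 1000
      arc_um <- seq(0, 8 * cone_width_hint_um, by = spacing)
      pts <- t(vapply(arc_um, function(a) {
        dd <- rotation_about(axis, a / width_r_mid_um) %*% d
        center_mm + r_mid_mm * as.numeric(dd)
      }, numeric(3)))
      vals <- trilinear_cpp(as.numeric(volume$data),
                            as.integer(dim(volume$data)),
                            mm_to_index(volume, pts))
      meas <- tryCatch(
        measure_layer(vals, spacing, min_contrast = 0.04,
                      dynamic_range = 65535,
                      min_separation_um = 1.5 * volume$voxel_size_um),
        error = function(e) NULL)
      if (is.null(meas) || length(meas$thicknesses_um) < 1) next
      rows[[length(rows) + 1]] <- tibble(
        specimen_id = specimen_id,
        slice_id = sprintf("width%02d", k),
        region = width_regions[k],
        structure = "cone",
        dimension = "width",
        value_um = stats::median(meas$thicknesses_um)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full pipeline on a project manifest
#'
#' Per specimen: calibrate pixel scale, measure ITD and 2D DRA area,
#' extract the eye mesh from the label volume, estimate the camera pose
#' from the ocelli, project the 3D-segmentation annotation onto the mesh,
#' measure 3D DRA and whole-eye areas, assign region bands, extract virtual
#' slices with rhabdom-continuity QC, and measure ommatidial structures per
#' region. Then across specimens: the paired 2D-vs-3D comparison, the
#' region comparison of cone thickness, and the allometric fits. Failed
#' stages are recorded per specimen without aborting the cohort.
#'
#' @param manifest data frame or CSV path with columns `specimen_id`,
#'   `photo`, `mask_2d`, `mask_3d`, `landmarks`, `volume`, `label` (and
#'   optionally `truth`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for CSV reports (with JSON sidecars).
#' @return a `dra_pipeline_report`: list with `specimens` (one row per
#'   specimen), `measurements` (tidy table), `stats` (comparison and fit
#'   objects) and `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  validate_config(config)
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) abort("config error: empty manifest")
  need <- c("specimen_id", "mask_2d", "mask_3d", "landmarks", "volume", "label")
  if (!all(need %in% names(manifest)))
    abort(paste("config error: manifest must have columns",
                paste(need, collapse = ", ")))
  if (anyDuplicated(manifest$specimen_id))
    abort("config error: specimen_id values must be unique")
  for (p in unlist(manifest[need[-1]])) {
    if (!file.exists(p)) abort(paste("config error: missing input file", p))
  }

  spec_rows <- list()
  meas_rows <- list()
  for (s in seq_len(nrow(manifest))) {
    sid <- manifest$specimen_id[s]
    rec <- list(specimen_id = sid, itd_mm = NA_real_,
                size_class = NA_character_, mm_per_px = NA_real_,
                calib_residual_px = NA_real_, area_2d_mm2 = NA_real_,
                dra_area_3d_mm2 = NA_real_, eye_area_3d_mm2 = NA_real_,
                pose_residual_px = NA_real_, pose_flagged = NA,
                n_slices_pass = NA_integer_, error = NA_character_)
    res <- tryCatch({
      lmdoc <- read_landmarks_json(manifest$landmarks[s])
      scale <- calibrate_scale(lmdoc$grid_points, config$grid_pitch_mm)
      rec$mm_per_px <- scale$mm_per_px
      rec$calib_residual_px <- scale$fit_residual_px
      thorax_scale <- calibrate_scale(lmdoc$thorax_grid_points,
                                      config$thorax_grid_pitch_mm)
      rec$itd_mm <- measure_itd(lmdoc$tegula_left_px, lmdoc$tegula_right_px,
                                thorax_scale)
      rec$size_class <- classify_size(rec$itd_mm)
      mask2d <- read_image_png(manifest$mask_2d[s], as_mask = TRUE)
      rec$area_2d_mm2 <- measure_area_2d(mask2d, scale)

      label <- read_volume_tiff(manifest$label[s])
      mesh <- label_to_mesh(label)
      lms <- landmark_set(lmdoc$points_3d_mm, lmdoc$points_2d_px)
      pose <- estimate_pose(lms, mesh,
                            flag_threshold_px = config$flag_threshold_px)
      rec$pose_residual_px <- pose$residual_px
      rec$pose_flagged <- pose$flagged
      mask3d <- read_image_png(manifest$mask_3d[s], as_mask = TRUE)
      mesh <- project_mask(mesh, pose, mask3d)
      rec$dra_area_3d_mm2 <- region_area(mesh, "DRA")
      rec$eye_area_3d_mm2 <- mesh_area(mesh)
      bands <- region_bands(config$facet_pitch_mm, config$proximate_rows,
                            config$non_dra_rows)
      mesh <- assign_region(mesh, bands)

      volume <- read_volume_tiff(manifest$volume[s])
      center <- colMeans(mesh$vertices)
      cen <- face_centroids(mesh)
      rel <- sweep(cen, 2, center)
      radii <- sqrt(rowSums(rel^2))
      outer_radius_um <- stats::median(radii) * 1000
      dra_dir <- normalize(colMeans(rel[mesh$face_region == "DRA", , drop = FALSE]))

      # virtual slices fanned about the DRA axis, with rhabdom QC
      b <- orthobasis(dra_dir)
      n_pass <- 0L
      for (k in seq_len(config$n_slices)) {
        phi <- (k - 1) * pi / config$n_slices
        a2 <- cos(phi) * b$e1 + sin(phi) * b$e2
        pl <- slice_plane(center, dra_dir, a2,
                          rep(2.4 * outer_radius_um / 1000, 2),
                          volume$voxel_size_um)
        sl <- extract_slice(volume, pl)
        qc <- tryCatch(
          check_rhabdom_continuity(sl, config$rhabdom_band,
                                   config$gap_tolerance_um),
          error = function(e) NULL)
        if (!is.null(qc) && qc$pass) n_pass <- n_pass + 1L
      }
      rec$n_slices_pass <- n_pass

      # structure measurements per region along face-normal profiles
      seeds <- child_seeds(config$seed + s, 1L)
      regions3 <- c("DRA", "proximate", "non_DRA")
      dirs <- NULL; regs <- character(0)
      wdirs <- NULL; wregs <- character(0)
      with_seed(seeds[1], {
        for (rg in regions3) {
          idx <- which(mesh$face_region == rg)
          if (length(idx) == 0) next
          pick <- sample(idx, min(config$profiles_per_region, length(idx)))
          dirs <- rbind(dirs, rel[pick, , drop = FALSE])
          regs <- c(regs, rep(rg, length(pick)))
          if (rg %in% config$width_regions) {
            wpick <- sample(idx, 1)
            wdirs <- rbind(wdirs, rel[wpick, , drop = FALSE])
            wregs <- c(wregs, rg)
          }
        }
      })
      tjson <- if ("truth" %in% names(manifest) && file.exists(manifest$truth[s]))
        jsonlite::read_json(manifest$truth[s], simplifyVector = TRUE) else NULL
      lt_sum <- if (!is.null(tjson)) sum(unlist(tjson$layer_thicknesses_um)) else
        0.55 * outer_radius_um
      width_r_mid <- outer_radius_um -
        (if (!is.null(tjson)) tjson$layer_thicknesses_um$lens +
           tjson$layer_thicknesses_um$cone / 2 else 0.2 * outer_radius_um)
      cone_hint <- if (!is.null(tjson)) tjson$cone_width_um else 8
      mm <- measure_structures(
        volume, center, dirs, regs, outer_radius_um,
        depth_um = lt_sum + 30 * volume$voxel_size_um,
        dra_axis = dra_dir, min_contrast = config$min_contrast,
        specimen_id = sid,
        width_directions = wdirs, width_regions = wregs,
        width_r_mid_um = width_r_mid, cone_width_hint_um = cone_hint)
      mm
    }, error = function(e) {
      rec$error <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) meas_rows[[length(meas_rows) + 1]] <- res
    spec_rows[[s]] <- as_tibble(rec)
  }
  specimens <- dplyr::bind_rows(spec_rows)
  measurements <- dplyr::bind_rows(meas_rows)

  stats_out <- list()
  ok <- !is.na(specimens$area_2d_mm2) & !is.na(specimens$dra_area_3d_mm2)
  if (sum(ok) >= 2) {
    stats_out$equivalence_2d_3d <- paired_signed_rank(
      specimens$area_2d_mm2[ok], specimens$dra_area_3d_mm2[ok])
  }
  if (nrow(measurements) > 0 &&
      length(unique(measurements$region[measurements$structure == "cone"])) >= 2) {
    stats_out$cone_thickness_regions <- tryCatch(
      region_comparison(measurements, "cone", "thickness"),
      error = function(e) NULL)
  }
  okf <- ok & !is.na(specimens$itd_mm)
  if (sum(okf) >= 3) {
    stats_out$dra_allometry <- fit_allometry(specimens$itd_mm[okf],
                                             specimens$area_2d_mm2[okf])
    stats_out$eye_allometry <- fit_allometry(specimens$itd_mm[okf],
                                             specimens$eye_area_3d_mm2[okf])
  }
  report <- structure(
    list(specimens = specimens, measurements = measurements,
         stats = stats_out, config = config),
    class = "dra_pipeline_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_sidecar(specimens, file.path(out_dir, "specimens.csv"),
                           seed = config$seed, config = config)
    write_csv_with_sidecar(measurements, file.path(out_dir, "measurements.csv"),
                           seed = config$seed, config = config)
  }
  report
}

#' @export
print.dra_pipeline_report <- function(x, ...) {
  cat("<dra_pipeline_report>", nrow(x$specimens), "specimens,",
      nrow(x$measurements), "measurements\n")
  failed <- sum(!is.na(x$specimens$error))
  if (failed > 0) cat(" ", failed, "specimen(s) with failed stages\n")
  if (!is.null(x$stats$equivalence_2d_3d)) {
    cat("  2D vs 3D DRA area: W =", x$stats$equivalence_2d_3d$statistic,
        "p =", format(x$stats$equivalence_2d_3d$p_value, digits = 4), "\n")
  }
  if (!is.null(x$stats$cone_thickness_regions)) {
    cat("  cone thickness regions: H =",
        format(x$stats$cone_thickness_regions$kw$statistic, digits = 5),
        "p =", format(x$stats$cone_thickness_regions$kw$p_value, digits = 4), "\n")
  }
  invisible(x)
}

#' Mesh-level validation cohort: 2D planimetry vs 3D surface area
#'
#' Builds paper-scale head phantoms (two per size class), photographs each
#' close-up under a known pose, emulates two independent manual annotations
#' of the grey DRA patch, and measures the DRA area both ways: 2D
#' planimetry of the photo annotation (via grid calibration), and 3D
#' surface area of the faces labeled by projecting the second annotation
#' through the pose estimated from noisy ocelli clicks. Exact projections
#' and analytic truth are carried along for the deterministic
#' projection-inequality checks.
#'
#' @param n_per_class specimens per size class.
#' @param theta_range DRA cap angular radii across the cohort (near-flat
#'   patches).
#' @param annotation_sd_px manual-annotation boundary jitter.
#' @param landmark_noise_px ocelli click noise.
#' @param image_size close-up frame (px).
#' @param subdivisions mesh refinement.
#' @param seed master seed.
#' @return tibble, one row per specimen: measured `area_2d_mm2`,
#'   `area_3d_mm2`, exact `planimetric_mm2` (rendered-mask area),
#'   `true_dra_mm2` (analytic cap), plus identifiers.
#' @export
make_equivalence_cohort <- function(n_per_class = 2L,
                                    theta_range = c(0.15, 0.25),
                                    annotation_sd_px = 2,
                                    landmark_noise_px = 0.3,
                                    image_size = c(560, 560),
                                    subdivisions = 5L,
                                    seed = 1L) {
  n <- 3L * n_per_class
  bounds <- size_class_bounds()
  seeds <- child_seeds(seed, n * 4L + 1L)
  itd <- with_seed(seeds[n * 4L + 1L], {
    unlist(lapply(1:3, function(k) {
      runif(n_per_class, bounds[k] + 0.1, bounds[k + 1] - 0.1)
    }))
  })
  thetas <- seq(theta_range[1], theta_range[2], length.out = n)
  rows <- list()
  for (s in seq_len(n)) {
    sb <- (s - 1L) * 4L
    R <- 0.25 * itd[s]
    params <- phantom_params(
      eye_radius_mm = R,
      dra_angular_radius_rad = thetas[s],
      facet_pitch_mm = 0.025,
      seed = seeds[sb + 1]
    )
    params$ocelli_mm <- closeup_ocelli(R, params$dra_center_direction, thetas[s])
    truth <- make_head_phantom(params, subdivisions = subdivisions,
                               image_size = image_size)
    scale <- 0.21 * min(image_size) / (R * sin(thetas[s]))
    pose <- pose_toward(params$dra_center_direction, scale, image_size,
                        tilt_rad = 0.10)
    rv <- render_view(truth, pose, image_size)

    grid_pts <- synthetic_grid_points(scale, 0.02, seed = seeds[sb + 2])
    cal <- calibrate_scale(grid_pts, 0.02)
    mask2d <- annotate_mask(rv$mask, annotation_sd_px, seed = seeds[sb + 2])
    area2d <- measure_area_2d(mask2d, cal)

    mask3d <- annotate_mask(rv$mask, annotation_sd_px, seed = seeds[sb + 3])
    nlm <- nrow(rv$landmark_px)
    lm2 <- rv$landmark_px + with_seed(seeds[sb + 4],
                                      matrix(rnorm(2 * nlm, 0, landmark_noise_px), nlm, 2))
    rownames(lm2) <- rownames(rv$landmark_px)
    blank <- set_face_region(truth$mesh, seq_len(nrow(truth$mesh$faces)),
                             "unlabeled")
    pose_est <- estimate_pose(landmark_set(phantom_landmarks_mm(params), lm2), blank)
    labeled <- project_mask(blank, pose_est, mask3d)
    area3d <- region_area(labeled, "DRA")

    rows[[s]] <- tibble(
      specimen_id = sprintf("s%02d", s),
      itd_mm = itd[s],
      size_class = classify_size(itd[s]),
      theta = thetas[s],
      mm_per_px = cal$mm_per_px,
      area_2d_mm2 = area2d,
      area_3d_mm2 = area3d,
      planimetric_mm2 = sum(rv$mask) / scale^2,
      true_dra_mm2 = truth$true_dra_area_mm2
    )
  }
  dplyr::bind_rows(rows)
}
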