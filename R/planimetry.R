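#' Calibrate pixel scale from a grid paper
#'
#' Fits a similarity transform (rotation + isotropic scale + translation)
#' from lattice mm coordinates to the clicked pixel positions of grid
#' corners, by least squares. The grid is assumed to lie in the focal
#' plane; the RMS residual is reported so the operator can reject tilted
#' grids. The grid pitch is a required input (it is a property of the grid
#' paper used at acquisition).
#'
#' @param grid_points data frame with columns `i`, `j` (integer lattice
#'   indices) and `x_px`, `y_px` (clicked pixel positions).
#' @param grid_pitch_mm lattice pitch in mm (> 0).
#' @return an object of class `pixel_scale` with `mm_per_px`,
#'   `fit_residual_px`, `n_points` and `rotation_rad`.
#' @export
calibrate_scale <- function(grid_points, grid_pitch_mm) {
  if (!is.numeric(grid_pitch_mm) || grid_pitch_mm <= 0)
    abort("grid_pitch_mm must be positive")
  gp <- as.data.frame(grid_points)
  need <- c("i", "j", "x_px", "y_px")
  if (!all(need %in% names(gp)))
    abort("grid_points needs columns i, j, x_px, y_px")
  gp <- gp[complete.cases(gp[need]), , drop = FALSE]
  if (nrow(gp) < 3)
    abort("calibration error: need at least 3 grid points")
  ij <- cbind(gp$i, gp$j)
  ijc <- sweep(ij, 2, colMeans(ij))
  if (svd(ijc)$d[2] < 1e-9)
    abort("calibration error: grid points are collinear")
  zmm <- complex(real = gp$i, imaginary = gp$j) * grid_pitch_mm
  zpx <- complex(real = gp$x_px, imaginary = gp$y_px)
  zmc <- zmm - mean(zmm)
  zpc <- zpx - mean(zpx)
  alpha <- sum(Conj(zmc) * zpc) / sum(Mod(zmc)^2)  # px per mm, complex
  resid <- sqrt(mean(Mod(zpc - alpha * zmc)^2))
  structure(
    list(mm_per_px = 1 / Mod(alpha), fit_residual_px = resid,
         n_points = nrow(gp), rotation_rad = Arg(alpha)),
    class = "pixel_scale"
  )
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat("<pixel_scale> ", format(x$mm_per_px, digits = 6), " mm/px (",
      x$n_points, " points, residual ",
      format(x$fit_residual_px, digits = 3), " px)\n", sep = "")
  invisible(x)
}

#' Construct a pixel scale directly
#' @param mm_per_px millimetres per pixel (> 0).
#' @export
pixel_scale <- function(mm_per_px) {
  if (mm_per_px <= 0) abort("mm_per_px must be positive")
  structure(list(mm_per_px = mm_per_px, fit_residual_px = 0, n_points = 0L,
                 rotation_rad = 0), class = "pixel_scale")
}

#' Planimetric area of a binary annotation
#'
#' Counts mask pixels (pixel-center membership, no sub-pixel smoothing) and
#' converts to mm^2 with the calibrated scale.
#'
#' @param mask logical/binary matrix (rows = y, columns = x).
#' @param scale a [pixel_scale()] or [calibrate_scale()] result.
#' @return area in mm^2; an empty mask returns 0 with a warning.
#' @export
measure_area_2d <- function(mask, scale) {
  stopifnot(inherits(scale, "pixel_scale"))
  npx <- sum(mask > 0)
  if (npx == 0) warn("empty annotation mask; area is 0")
  npx * scale$mm_per_px^2
}

#' Inter-tegular distance from two annotated points
#'
#' Euclidean pixel distance between the two wing insertion points times the
#' calibrated scale; ITD is the standard body-size proxy in bees.
#'
#' @param point_a_px,point_b_px length-2 pixel coordinates.
#' @inheritParams measure_area_2d
#' @return distance in mm; identical points return 0 with a warning.
#' @export
measure_itd <- function(point_a_px, point_b_px, scale) {
  stopifnot(inherits(scale, "pixel_scale"))
  d <- sqrt(sum((as.numeric(point_a_px) - as.numeric(point_b_px))^2))
  if (d == 0) warn("zero inter-tegular distance: the two points coincide")
  d * scale$mm_per_px
}

#' Default body-size class bounds (mm)
#'
#' The study's ITD bins: small `[2.965, 3.902)`, medium `[3.902, 4.839)`,
#' large `[4.839, 5.776]`. Bins are half-open on the right, the last bin
#' closed (the published bins share their interior endpoints without a
#' stated tie rule).
#' @export
size_class_bounds <- function() {
  c(2.965, 3.902, 4.839, 5.776)
}

#' Classify a specimen into a body-size class by ITD
#'
#' @param itd_mm inter-tegular distance in mm (> 0).
#' @param bounds increasing numeric vector of 4 bin edges; defaults to
#'   [size_class_bounds()].
#' @return one of `"small"`, `"medium"`, `"large"`, or `"out_of_range"`
#'   (explicit, never silent) for values outside the bins.
#' @export
classify_size <- function(itd_mm, bounds = size_class_bounds()) {
  if (!is.numeric(itd_mm) || any(itd_mm <= 0)) abort("itd_mm must be positive")
  if (length(bounds) != 4 || is.unsorted(bounds)) abort("bounds must be 4 increasing edges")
  out <- rep("out_of_range", length(itd_mm))
  out[itd_mm >= bounds[1] & itd_mm < bounds[2]] <- "small"
  out[itd_mm >= bounds[2] & itd_mm < bounds[3]] <- "medium"
  out[itd_mm >= bounds[3] & itd_mm <= bounds[4]] <- "large"
  out
}
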