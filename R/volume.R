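#' 3D scalar image with isotropic voxel size
#'
#' Thin container around a 3D array. The array is indexed `[x, y, z]`; the
#' mm position of voxel `(i, j, k)` (1-based, voxel center) is
#' `origin_mm + (c(i, j, k) - 1) * voxel_size_um / 1000`. On disk, volumes
#' are multipage TIFFs with one z-slice per page, rows = y, columns = x
#' (see [write_volume_tiff()]).
#'
#' @param data 3D numeric array, gray values (0..65535 for 16-bit sources).
#' @param voxel_size_um isotropic voxel size in micrometres (> 0).
#' @param origin_mm mm position of the center of voxel (1, 1, 1).
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_um, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3) abort("data must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      voxel_size_um <= 0)
    abort("voxel_size_um must be a positive scalar")
  if (length(origin_mm) != 3) abort("origin_mm must be a 3-vector")
  structure(
    list(data = data, voxel_size_um = voxel_size_um,
         origin_mm = as.numeric(origin_mm)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_image> ", paste(d, collapse = " x "),
      " voxels @ ", x$voxel_size_um, " um\n", sep = "")
  cat("  origin (mm):", paste(format(x$origin_mm, digits = 4), collapse = ", "), "\n")
  cat("  gray range:", paste(format(range(x$data), digits = 6), collapse = " .. "), "\n")
  invisible(x)
}

# mm coordinates -> fractional 1-based array indices.
mm_to_index <- function(volume, pts_mm) {
  vox_mm <- volume$voxel_size_um / 1000
  sweep(pts_mm, 2, volume$origin_mm) / vox_mm + 1
}

index_to_mm <- function(volume, idx) {
  vox_mm <- volume$voxel_size_um / 1000
  sweep((idx - 1) * vox_mm, 2, volume$origin_mm, "+")
}

#' Crop a volume to an index box
#'
#' Plumbing replacement for interactive ROI cropping: returns the sub-volume
#' spanned by the inclusive 1-based index ranges, with the origin updated so
#' mm coordinates are preserved.
#'
#' @param volume a [volume_image()].
#' @param x,y,z length-2 integer ranges (inclusive); `NULL` keeps the full
#'   extent along that axis.
#' @export
crop_volume <- function(volume, x = NULL, y = NULL, z = NULL) {
  d <- dim(volume$data)
  rng <- function(r, n) {
    if (is.null(r)) return(c(1L, n))
    r <- as.integer(r)
    if (length(r) != 2 || r[1] < 1 || r[2] > n || r[1] > r[2])
      abort("crop range out of bounds")
    r
  }
  rx <- rng(x, d[1]); ry <- rng(y, d[2]); rz <- rng(z, d[3])
  vox_mm <- volume$voxel_size_um / 1000
  volume_image(
    volume$data[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE],
    volume$voxel_size_um,
    volume$origin_mm + (c(rx[1], ry[1], rz[1]) - 1) * vox_mm
  )
}
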