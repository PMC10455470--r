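# Standard-format plumbing: PNG masks/rasters, multipage 16-bit TIFF
# volumes with a JSON metadata sidecar, JSON landmark files.
# Volume TIFF convention: one z slice per page, rows = y, columns = x;
# in-memory arrays are indexed [x, y, z] (see volume_image()).

#' Write a binary mask or gray raster as PNG
#' @param img logical or numeric matrix (rows = y); numeric values are
#'   clamped to `[0, 1]`.
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  m <- clamp(matrix(as.numeric(img), nrow(img), ncol(img)), 0, 1)
  png::writePNG(m, path)
  invisible(path)
}

#' Read a PNG as a gray matrix or binary mask
#' @param path PNG file.
#' @param as_mask threshold at 0.5 and return logical.
#' @export
read_image_png <- function(path, as_mask = FALSE) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (as_mask) m > 0.5 else m
}

#' Write a volume as multipage 16-bit TIFF plus JSON metadata
#'
#' Gray values are stored scaled by 1/65535; the sidecar
#' (`<path>.json`) records `voxel_size_um` and `origin_mm`.
#'
#' @param volume a [volume_image()].
#' @param path output TIFF path.
#' @export
write_volume_tiff <- function(volume, path) {
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[3]), function(k) t(volume$data[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size_um, origin_mm = volume$origin_mm,
         dim = d, gray_scale = 65535),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#' @param path TIFF path (expects `<path>.json` sidecar).
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- aperm(simplify2array(pages), c(2, 1, 3)) * meta$gray_scale
  volume_image(arr, meta$voxel_size_um, meta$origin_mm)
}

#' Write named landmarks as JSON
#'
#' 2D points are stored as `{name: [x_px, y_px]}` under `points_2d_px`,
#' 3D points as `{name: [x_mm, y_mm, z_mm]}` under `points_3d_mm`.
#'
#' @param path output JSON file.
#' @param points_2d_px,points_3d_mm named matrices (rownames = landmark
#'   names), either may be `NULL`.
#' @param extra optional named list merged into the JSON document.
#' @export
write_landmarks_json <- function(path, points_2d_px = NULL,
                                 points_3d_mm = NULL, extra = list()) {
  tolist <- function(m) {
    if (is.null(m)) return(NULL)
    setNames(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
             rownames(m))
  }
  doc <- c(list(points_2d_px = tolist(points_2d_px),
                points_3d_mm = tolist(points_3d_mm)), extra)
  jsonlite::write_json(doc[!vapply(doc, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark JSON file
#' @param path JSON file written by [write_landmarks_json()].
#' @return list with `points_2d_px` / `points_3d_mm` as named matrices plus
#'   any extra fields.
#' @export
read_landmarks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tomat <- function(lst) {
    if (is.null(lst)) return(NULL)
    do.call(rbind, lapply(lst, as.numeric))
  }
  doc$points_2d_px <- tomat(doc$points_2d_px)
  doc$points_3d_mm <- tomat(doc$points_3d_mm)
  doc
}

# CSV + JSON sidecar with version / seed / config hash, so every table is
# traceable to the run that produced it.
write_csv_with_sidecar <- function(df, path, seed = NULL, config = NULL) {
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(tool = "dramorph",
         version = as.character(utils::packageVersion("dramorph")),
         seed = seed,
         config_hash = if (!is.null(config))
           rlang::hash(config) else NULL,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
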