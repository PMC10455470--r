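#' Triangulated eye-surface mesh
#'
#' A `surface_mesh` holds a triangulated surface in mm together with an
#' optional per-face region label (`DRA`, `proximate`, `buffer`, `non_DRA`,
#' `unlabeled`). Meshes come either from the phantom generator or from
#' [label_to_mesh()] applied to a segmented micro-CT label volume.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param face_region optional character/factor of length m with values in
#'   `c("DRA", "proximate", "buffer", "non_DRA", "unlabeled")`.
#' @param clean drop zero-area (degenerate) faces.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, face_region = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) abort("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3) abort("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    abort("face indices out of range")
  if (is.null(face_region)) {
    face_region <- factor(rep("unlabeled", nrow(faces)), levels = region_levels())
  } else {
    face_region <- factor(as.character(face_region), levels = region_levels())
    if (anyNA(face_region)) abort("unknown face_region label")
    if (length(face_region) != nrow(faces))
      abort("face_region must have one label per face")
  }
  mesh <- structure(
    list(vertices = vertices, faces = faces, face_region = face_region),
    class = "surface_mesh"
  )
  if (clean && nrow(faces) > 0) {
    keep <- face_areas(mesh) > 0
    if (!all(keep)) {
      mesh$faces <- mesh$faces[keep, , drop = FALSE]
      mesh$face_region <- mesh$face_region[keep]
    }
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  tab <- table(droplevels(x$face_region))
  if (length(tab) > 1 || names(tab)[1] != "unlabeled") {
    cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  total area:", format(mesh_area(x), digits = 6), "mm^2\n")
  invisible(x)
}

# Per-face corner matrices (each m x 3).
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Per-face triangle areas in mm^2
#' @param mesh a [surface_mesh()].
#' @return numeric vector of length `nrow(mesh$faces)`.
#' @export
face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(numeric(0))
  cr <- face_corners(mesh)
  cp <- cross3_rows(cr$b - cr$a, cr$c - cr$a)
  sqrt(rowSums(cp^2)) / 2
}

#' Per-face unit normals (direction given by vertex winding)
#' @inheritParams face_areas
#' @export
face_normals <- function(mesh) {
  cr <- face_corners(mesh)
  cp <- cross3_rows(cr$b - cr$a, cr$c - cr$a)
  n <- sqrt(rowSums(cp^2))
  n[n == 0] <- 1
  cp / n
}

#' Per-face centroids in mm
#' @inheritParams face_areas
#' @export
face_centroids <- function(mesh) {
  cr <- face_corners(mesh)
  (cr$a + cr$b + cr$c) / 3
}

#' Total mesh surface area
#'
#' Sum of triangle areas via the cross-product formula
#' \eqn{\|(v_1-v_0)\times(v_2-v_0)\|/2}. An empty mesh has area 0.
#'
#' @inheritParams face_areas
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh))
}

#' Surface area of one labeled region
#'
#' Triangle-area sum restricted to faces carrying the given region label.
#' Region areas over all labels (including `unlabeled`) sum exactly to
#' [mesh_area()].
#'
#' @inheritParams face_areas
#' @param region one of `"DRA"`, `"proximate"`, `"buffer"`, `"non_DRA"`,
#'   `"unlabeled"`.
#' @return area in mm^2.
#' @export
region_area <- function(mesh, region) {
  if (!is.character(region) || length(region) != 1 ||
      !(region %in% region_levels()))
    abort(paste0("unknown region label; expected one of: ",
                 paste(region_levels(), collapse = ", ")))
  sum(face_areas(mesh)[mesh$face_region == region])
}

#' Assign a region label to a set of faces
#' @inheritParams face_areas
#' @param face_idx integer indices of faces to relabel.
#' @param region label from the region vocabulary.
#' @export
set_face_region <- function(mesh, face_idx, region) {
  if (!(region %in% region_levels())) abort("unknown region label")
  fr <- as.character(mesh$face_region)
  fr[face_idx] <- region
  mesh$face_region <- factor(fr, levels = region_levels())
  mesh
}

# Flip faces so normals point away from `center` (used for star-shaped
# surfaces like the phantom eye and label isosurfaces of convex bodies).
orient_outward <- function(mesh, center = NULL) {
  if (is.null(center)) center <- colMeans(mesh$vertices)
  nrm <- face_normals(mesh)
  cen <- sweep(face_centroids(mesh), 2, center)
  flip <- rowSums(nrm * cen) < 0
  mesh$faces[flip, ] <- mesh$faces[flip, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Extract a surface mesh from a binary label volume
#'
#' Runs a marching-tetrahedra isosurface at `level` (0.5 between the binary
#' labels by default) and scales vertices into mm using the volume's voxel
#' size and origin. The binary label is passed through a small Gaussian
#' anti-aliasing filter (in the volume domain, `presmooth_sigma` voxels)
#' before extraction so that areas of curved surfaces converge to their
#' analytic values; no mesh-domain smoothing is performed.
#'
#' @param label_volume a [volume_image()] whose data is binary (or
#'   thresholdable at `level`).
#' @param level iso level, default 0.5.
#' @param presmooth_sigma Gaussian sigma in voxels applied to the label
#'   before extraction; `0` disables the filter.
#' @return a [surface_mesh()] in mm, cleaned of degenerate faces, with
#'   outward-oriented faces.
#' @export
label_to_mesh <- function(label_volume, level = 0.5, presmooth_sigma = 0.7) {
  stopifnot(inherits(label_volume, "volume_image"))
  dat <- label_volume$data
  rng <- range(dat)
  if (rng[1] > level || rng[2] <= level)
    abort("label volume has no foreground at the requested level")
  dims <- dim(dat)
  border <- c(dat[1, , ], dat[dims[1], , ], dat[, 1, ], dat[, dims[2], ],
              dat[, , 1], dat[, , dims[3]])
  if (any(border > level))
    warn("foreground touches the volume border; extracted surface will be open")
  if (presmooth_sigma > 0) {
    dat <- gauss_smooth3d_cpp(as.numeric(dat), as.integer(dims), presmooth_sigma)
  }
  res <- march_tets_cpp(as.numeric(dat), as.integer(dims), level)
  if (nrow(res$vertices) == 0) abort("isosurface extraction produced no faces")
  vox_mm <- label_volume$voxel_size_um / 1000
  verts <- sweep((res$vertices - 1) * vox_mm, 2, label_volume$origin_mm, "+")
  mesh <- surface_mesh(verts, res$faces, clean = TRUE)
  orient_outward(mesh)
}

#' Write a mesh as ASCII PLY
#'
#' Vertices are written in mm; the per-face region label is stored as an
#' integer `region` property (0 = unlabeled, 1 = DRA, 2 = proximate,
#' 3 = buffer, 4 = non_DRA).
#'
#' @inheritParams face_areas
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  codes <- c(DRA = 1L, proximate = 2L, buffer = 3L, non_DRA = 4L, unlabeled = 0L)
  reg <- codes[as.character(mesh$face_region)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment units mm",
    paste("element vertex", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "property int region",
    "end_header"
  ), con)
  writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L, reg), con)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#' @param path PLY file.
#' @return a [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) abort("not a PLY file (no end_header)")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  has_region <- any(grepl("^property int region", header))
  vtxt <- lines[end + seq_len(nv)]
  ftxt <- lines[end + nv + seq_len(nf)]
  verts <- matrix(scan(text = vtxt, quiet = TRUE), ncol = 3, byrow = TRUE)
  fw <- 4L + has_region
  fmat <- matrix(scan(text = ftxt, quiet = TRUE), ncol = fw, byrow = TRUE)
  faces <- fmat[, 2:4, drop = FALSE] + 1L
  region <- NULL
  if (has_region) {
    names_by_code <- c(`0` = "unlabeled", `1` = "DRA", `2` = "proximate",
                       `3` = "buffer", `4` = "non_DRA")
    region <- names_by_code[as.character(fmat[, 5])]
  }
  surface_mesh(verts, faces, region, clean = FALSE)
}
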