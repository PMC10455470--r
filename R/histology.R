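#' Define a virtual-histology slice plane
#'
#' @param origin_mm plane origin (mm, the center of the sampled patch).
#' @param u_axis,v_axis orthonormal in-plane unit vectors.
#' @param extent_mm `(width, height)` of the sampled patch in mm.
#' @param sample_spacing_um in-plane sample spacing; must not exceed the
#'   voxel size of the volume it is applied to (no undersampling).
#' @export
slice_plane <- function(origin_mm, u_axis, v_axis, extent_mm,
                        sample_spacing_um) {
  u <- as.numeric(u_axis); v <- as.numeric(v_axis)
  if (abs(vec_norm(u) - 1) > 1e-6 || abs(vec_norm(v) - 1) > 1e-6)
    abort("u_axis and v_axis must be unit vectors")
  if (abs(sum(u * v)) > 1e-6) abort("u_axis and v_axis must be orthogonal")
  if (sample_spacing_um <= 0) abort("sample_spacing_um must be positive")
  if (any(extent_mm <= 0)) abort("extent_mm must be positive")
  structure(
    list(origin_mm = as.numeric(origin_mm), u_axis = u, v_axis = v,
         extent_mm = as.numeric(extent_mm),
         sample_spacing_um = sample_spacing_um),
    class = "slice_plane"
  )
}

#' Extract a virtual histological slice from a volume
#'
#' Samples the volume by trilinear interpolation on the plane's regular
#' grid. Samples falling outside the volume are `NA` (marked invalid, not
#' zero-filled). This is the digital counterpart of a clipping-plane view
#' in volume-rendering software.
#'
#' @param volume a [volume_image()].
#' @param plane a [slice_plane()]; its sample spacing must not exceed the
#'   voxel size.
#' @return numeric matrix (rows = v, columns = u) with attributes
#'   `sample_spacing_um`, `u_mm`, `v_mm` (sample center coordinates along
#'   the two in-plane axes) and `plane`.
#' @export
extract_slice <- function(volume, plane) {
  stopifnot(inherits(volume, "volume_image"), inherits(plane, "slice_plane"))
  if (plane$sample_spacing_um > volume$voxel_size_um + 1e-9)
    abort("sample_spacing_um exceeds voxel size (undersampling)")
  sp_mm <- plane$sample_spacing_um / 1000
  us <- seq(-plane$extent_mm[1] / 2, plane$extent_mm[1] / 2, by = sp_mm)
  vs <- seq(-plane$extent_mm[2] / 2, plane$extent_mm[2] / 2, by = sp_mm)
  uu <- rep(us, each = length(vs))
  vv <- rep(vs, times = length(us))
  pts_mm <- cbind(plane$origin_mm[1] + uu * plane$u_axis[1] + vv * plane$v_axis[1],
                  plane$origin_mm[2] + uu * plane$u_axis[2] + vv * plane$v_axis[2],
                  plane$origin_mm[3] + uu * plane$u_axis[3] + vv * plane$v_axis[3])
  idx <- mm_to_index(volume, pts_mm)
  vals <- trilinear_cpp(as.numeric(volume$data), as.integer(dim(volume$data)), idx)
  m <- matrix(vals, nrow = length(vs), ncol = length(us))
  if (all(is.na(m))) abort("empty slice: the plane does not intersect the volume")
  attr(m, "sample_spacing_um") <- plane$sample_spacing_um
  attr(m, "u_mm") <- us
  attr(m, "v_mm") <- vs
  attr(m, "plane") <- plane
  m
}

# Least-squares (Kasa) circle fit; returns center (x, y) and radius in the
# given coordinate units.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(cx = sol[1], cy = sol[2], r = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
}

#' Rhabdom continuity quality control
#'
#' Traces the rhabdom gray-level band in a slice along its arc (the band of
#' an intact layer is an annulus arc in a longitudinal slice) and fails the
#' slice iff any along-band gap exceeds `gap_tolerance_um`. Only slices
#' that pass are meant to enter further analysis.
#'
#' @param slice matrix from [extract_slice()].
#' @param band_range gray-level range `c(lo, hi)` identifying rhabdom
#'   pixels.
#' @param gap_tolerance_um largest acceptable along-band gap; default twice
#'   the sample spacing.
#' @param closed treat the band as a closed loop (default) or an open arc.
#' @return object of class `dra_qc`: `pass`, `gaps_um` (all gaps above
#'   tolerance), `largest_gap_um`, `n_band_px`.
#' @export
check_rhabdom_continuity <- function(slice, band_range,
                                     gap_tolerance_um = NULL,
                                     closed = TRUE) {
  spacing <- attr(slice, "sample_spacing_um")
  if (is.null(spacing)) abort("slice lacks a sample_spacing_um attribute")
  if (is.null(gap_tolerance_um)) gap_tolerance_um <- 2 * spacing
  inb <- !is.na(slice) & slice >= band_range[1] & slice <= band_range[2]
  if (!any(inb))
    abort("QC error: no pixels fall in the rhabdom band range")
  idx <- which(inb, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  circ <- fit_circle(x, y)
  ang <- atan2(y - circ["cy"], x - circ["cx"])
  rad <- sqrt((x - circ["cx"])^2 + (y - circ["cy"])^2)
  r_mid <- stats::median(rad)
  s <- sort(ang * r_mid)  # arc-length positions in px units
  gaps <- diff(s)
  if (closed && length(s) > 1)
    gaps <- c(gaps, (s[1] + 2 * pi * r_mid) - s[length(s)])
  gaps_um <- gaps * spacing
  big <- gaps_um[gaps_um > gap_tolerance_um]
  structure(
    list(pass = length(big) == 0, gaps_um = big,
         largest_gap_um = if (length(gaps_um)) max(gaps_um) else 0,
         n_band_px = nrow(idx), gap_tolerance_um = gap_tolerance_um),
    class = "dra_qc"
  )
}

#' @export
print.dra_qc <- function(x, ...) {
  cat("<dra_qc> rhabdom continuity:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  band pixels:", x$n_band_px, " largest gap:",
      format(x$largest_gap_um, digits = 4), "um (tolerance",
      format(x$gap_tolerance_um, digits = 4), "um)\n")
  if (!x$pass)
    cat("  gaps above tolerance (um):",
        paste(format(x$gaps_um, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Measure layer boundaries and thicknesses along a 1D profile
#'
#' Boundaries are placed at local maxima of the gradient magnitude, with a
#' minimum-contrast guard (a fraction of the stated dynamic range) so that
#' noise edges are ignored, and refined to sub-sample precision by a
#' parabolic fit around each gradient peak. Thicknesses are distances
#' between consecutive boundaries.
#'
#' @param profile numeric vector of gray values sampled along a line.
#' @param spacing_um distance between consecutive samples (um).
#' @param min_contrast minimum step amplitude as a fraction of
#'   `dynamic_range` for a gradient peak to count as a boundary.
#' @param dynamic_range gray range used by the contrast guard; defaults to
#'   the range of the profile.
#' @param min_separation_um merge gradient peaks closer than this.
#' @return list of class `layer_measurement`: `boundaries_um` (positions
#'   along the profile), `thicknesses_um` (between consecutive boundaries).
#' @export
measure_layer <- function(profile, spacing_um, min_contrast = 0.10,
                          dynamic_range = NULL, min_separation_um = NULL) {
  profile <- as.numeric(profile)
  ok <- is.finite(profile)
  if (sum(ok) < 5) abort("measurement failure: profile too short")
  if (is.null(dynamic_range)) dynamic_range <- diff(range(profile[ok]))
  if (is.null(min_separation_um)) min_separation_um <- 6 * spacing_um
  n <- length(profile)
  # light symmetric smoothing before the gradient: suppresses noise-induced
  # twin maxima on one edge without moving the edge center
  sm <- as.numeric(stats::filter(profile, rep(1 / 3, 3)))
  sm[is.na(sm)] <- profile[is.na(sm)]
  g <- rep(NA_real_, n)
  g[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2
  ag <- abs(g)
  # local maxima of |gradient|
  cand <- which(!is.na(ag) & ag > 0 & ag >= c(NA, ag[-n]) & ag >= c(ag[-1], NA))
  if (length(cand) == 0)
    abort("measurement failure: no gradient maxima in the profile")
  # merge peaks closer than min_separation, keeping the strongest
  ord <- cand[order(-ag[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!any(abs(i - kept) * spacing_um < min_separation_um))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  # plateau-amplitude guard: a boundary must separate plateaus that differ
  # by at least min_contrast * dynamic_range. Plateaus are estimated as the
  # median between this boundary and its neighbours (2-sample guard band),
  # so satellite peaks riding on a strong edge carry no amplitude of their
  # own and are dropped; iterate since segments change as peaks drop.
  seg_med <- function(from, to) {
    if (from > to) return(NA_real_)
    stats::median(sm[from:to], na.rm = TRUE)
  }
  repeat {
    if (length(kept) == 0)
      abort("measurement failure: no boundaries above the contrast guard")
    mids <- c(1L, as.integer(floor((kept[-length(kept)] + kept[-1]) / 2)), n)
    amp <- vapply(seq_along(kept), function(j) {
      i <- kept[j]
      left <- seg_med(mids[j], max(mids[j], i - 2L))
      right <- seg_med(min(mids[j + 1], i + 2L), mids[j + 1])
      abs(right - left)
    }, numeric(1))
    fail <- which(is.na(amp) | amp < min_contrast * dynamic_range)
    if (length(fail) == 0) break
    kept <- kept[-fail]
  }
  # parabolic sub-sample refinement on |gradient|
  pos <- vapply(kept, function(i) {
    if (i <= 1 || i >= n || is.na(ag[i - 1]) || is.na(ag[i + 1])) return(i - 1)
    denom <- ag[i - 1] - 2 * ag[i] + ag[i + 1]
    delta <- if (abs(denom) > 1e-12) 0.5 * (ag[i - 1] - ag[i + 1]) / denom else 0
    (i - 1) + clamp(delta, -0.5, 0.5)
  }, numeric(1)) * spacing_um
  if (length(pos) < 2)
    abort("measurement failure: fewer than 2 boundaries found")
  structure(
    list(boundaries_um = pos, thicknesses_um = diff(pos)),
    class = "layer_measurement"
  )
}

#' @export
print.layer_measurement <- function(x, ...) {
  cat("<layer_measurement>", length(x$boundaries_um), "boundaries\n")
  cat("  positions (um):", paste(format(x$boundaries_um, digits = 5), collapse = ", "), "\n")
  cat("  thicknesses (um):", paste(format(x$thicknesses_um, digits = 5), collapse = ", "), "\n")
  invisible(x)
}

#' Manual two-point measurement
#'
#' Parity with interactive line measurements: Euclidean distance between
#' two operator-given sample coordinates times the sample spacing.
#'
#' @param point_a,point_b numeric coordinates (samples, any dimension).
#' @param um_per_sample spacing (um per sample step).
#' @return distance in um.
#' @export
measure_manual <- function(point_a, point_b, um_per_sample = 1) {
  sqrt(sum((as.numeric(point_a) - as.numeric(point_b))^2)) * um_per_sample
}

#' Sample a gray profile along a 3D line
#'
#' Convenience for layer measurements along a known direction (e.g. the
#' local surface normal): samples the volume from `start_mm` along
#' `direction` for `length_um` at `spacing_um`.
#'
#' @param volume a [volume_image()].
#' @param start_mm line start (mm).
#' @param direction 3-vector (normalized internally).
#' @param length_um line length (um).
#' @param spacing_um sample spacing (um), defaults to half the voxel size.
#' @return numeric vector of gray values with attribute `spacing_um`.
#' @export
extract_profile <- function(volume, start_mm, direction, length_um,
                            spacing_um = volume$voxel_size_um / 2) {
  dvec <- normalize(direction)
  tt <- seq(0, length_um, by = spacing_um) / 1000
  pts <- cbind(start_mm[1] + tt * dvec[1],
               start_mm[2] + tt * dvec[2],
               start_mm[3] + tt * dvec[3])
  vals <- trilinear_cpp(as.numeric(volume$data), as.integer(dim(volume$data)),
                        mm_to_index(volume, pts))
  attr(vals, "spacing_um") <- spacing_um
  vals
}

#' External lens width between two surface points
#'
#' Euclidean 3D distance in um between two points on the eye surface, with
#' an off-surface warning when either point is farther from the mesh than
#' one voxel.
#'
#' @param mesh a [surface_mesh()].
#' @param point_a_mm,point_b_mm 3D points (mm).
#' @param voxel_size_um tolerance for the off-surface check.
#' @return width in um; identical points return 0 with a warning.
#' @export
measure_lens_width_3d <- function(mesh, point_a_mm, point_b_mm,
                                  voxel_size_um = 1.625) {
  dist_to_surface <- function(p) {
    d2 <- rowSums(sweep(mesh$vertices, 2, p)^2)
    sqrt(min(d2)) * 1000
  }
  da <- dist_to_surface(point_a_mm)
  db <- dist_to_surface(point_b_mm)
  if (max(da, db) > voxel_size_um)
    warn(sprintf("point lies %.3g um off the surface", max(da, db)))
  w <- sqrt(sum((as.numeric(point_a_mm) - as.numeric(point_b_mm))^2)) * 1000
  if (w == 0) warn("zero lens width: the two points coincide")
  w
}

#' Region band definition in ommatidial rows
#'
#' "Ommatidial rows" are operationalized as geodesic distance over the eye
#' surface in units of the facet pitch, since individual facets are not
#' segmented: proximate = within `proximate_rows` of the DRA boundary,
#' non-DRA = beyond `non_dra_rows`, buffer = the unclassified rows between.
#'
#' @param facet_pitch_mm center-to-center facet spacing (mm).
#' @param proximate_rows rows counted as proximate (default 5).
#' @param non_dra_rows rows beyond which faces are non-DRA (default 20).
#' @export
region_bands <- function(facet_pitch_mm, proximate_rows = 5L,
                         non_dra_rows = 20L) {
  if (facet_pitch_mm <= 0) abort("facet_pitch_mm must be positive")
  if (!(proximate_rows > 0 && proximate_rows < non_dra_rows))
    abort("need 0 < proximate_rows < non_dra_rows")
  structure(list(facet_pitch_mm = facet_pitch_mm,
                 proximate_rows = as.integer(proximate_rows),
                 non_dra_rows = as.integer(non_dra_rows)),
            class = "region_bands")
}

#' Assign eye-region labels by geodesic distance from the DRA
#'
#' For every face outside the DRA, computes the geodesic distance from the
#' DRA boundary over the face-adjacency graph (edge weights = centroid
#' distances) and labels it `proximate` (within `proximate_rows` x pitch),
#' `buffer` (rows `proximate_rows`..`non_dra_rows`, which the study's
#' classes leave unassigned) or `non_DRA` (beyond `non_dra_rows` x pitch).
#' "Vertically from the DRA" is interpreted as geodesic distance from the
#' DRA boundary, not a screen-axis direction.
#'
#' @param mesh a [surface_mesh()] with `DRA` faces labeled.
#' @param bands a [region_bands()].
#' @return the mesh with the full region partition set.
#' @export
assign_region <- function(mesh, bands) {
  stopifnot(inherits(bands, "region_bands"))
  dra <- which(mesh$face_region == "DRA")
  if (length(dra) == 0) abort("region error: no DRA faces labeled")
  nf <- nrow(mesh$faces)
  # face adjacency via shared edges
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  fid <- rep(seq_len(nf), 3)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  same <- key[-length(key)] == key[-1]
  pair_a <- fid[c(same, FALSE)]
  pair_b <- fid[c(FALSE, same)]
  cen <- face_centroids(mesh)
  wts <- sqrt(rowSums((cen[pair_a, , drop = FALSE] - cen[pair_b, , drop = FALSE])^2))
  # multi-source shortest path from the DRA boundary via a virtual source
  boundary <- unique(c(pair_a[pair_a %in% dra & !(pair_b %in% dra)],
                       pair_b[pair_b %in% dra & !(pair_a %in% dra)]))
  if (length(boundary) == 0) boundary <- dra
  eps <- 1e-9
  edges <- c(rbind(pair_a, pair_b), rbind(rep(nf + 1L, length(boundary)), boundary))
  g <- igraph::make_graph(edges = edges, n = nf + 1L, directed = FALSE)
  igraph::E(g)$weight <- c(wts, rep(eps, length(boundary)))
  d <- as.numeric(igraph::distances(g, v = nf + 1L, to = seq_len(nf)))
  pitch <- bands$facet_pitch_mm
  lab <- as.character(mesh$face_region)
  outside <- setdiff(seq_len(nf), dra)
  lab[outside] <- dplyr::case_when(
    d[outside] <= bands$proximate_rows * pitch ~ "proximate",
    d[outside] <= bands$non_dra_rows * pitch ~ "buffer",
    TRUE ~ "non_DRA"
  )
  mesh$face_region <- factor(lab, levels = region_levels())
  mesh
}
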