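# Shared fixtures, built once per test run.

# Default paper-scale head phantom (R = 1.2 mm, theta = 0.3, 20480 faces).
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_head_phantom(phantom_params())
    cache
  }
})

# Small layered volume phantom for histology tests (miniaturized eye).
histo_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pp <- phantom_params(eye_radius_mm = 0.16, dra_angular_radius_rad = 0.25,
                           facet_pitch_mm = 0.008,
                           layer_thicknesses_um = c(lens = 18, cone = 36, rhabdom = 50),
                           cone_width_um = 8)
      cache <<- make_volume_phantom(pp, dra_cone_scale = 0.8, seed = 42)
    }
    cache
  }
})

# Binary ball label volume of the given voxel radius.
ball_volume <- function(radius_vox, voxel_size_um = 1000, pad = 5) {
  n <- 2L * (radius_vox + pad) + 1L
  c0 <- radius_vox + pad + 1
  xs <- (1:n) - c0
  r <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  volume_image(array(as.numeric(r <= radius_vox), c(n, n, n)), voxel_size_um)
}

# Brute-force signed-rank oracle: exact two-sided p over all 2^n sign
# assignments of the |difference| midranks.
signed_rank_brute_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# A ring-band raster emulating a rhabdom band in a slice.
ring_slice <- function(n = 101, radius = 30, half_width = 1.5, value = 100,
                       spacing_um = 1, gap_deg = NULL) {
  m <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    r <- sqrt((i - c0)^2 + (j - c0)^2)
    if (abs(r - radius) <= half_width) {
      ang <- atan2(i - c0, j - c0) * 180 / pi
      if (is.null(gap_deg) || !(ang >= gap_deg[1] && ang <= gap_deg[2]))
        m[i, j] <- value
    }
  }
  attr(m, "sample_spacing_um") <- spacing_um
  m
}

# Bilinear sampling of a slice matrix along an in-plane direction through
# the slice center; returns the gray profile at step_um spacing.
slice_line <- function(sl, dir_uv, step_um, length_um = NULL) {
  us <- attr(sl, "u_mm"); vs <- attr(sl, "v_mm")
  sp <- us[2] - us[1]
  d <- dir_uv / sqrt(sum(dir_uv^2))
  if (is.null(length_um)) length_um <- 0.9 * min(diff(range(us)), diff(range(vs))) * 1000
  tt <- seq(-length_um / 2, length_um / 2, by = step_um) / 1000
  uu <- tt * d[1]; vv <- tt * d[2]
  ci <- (uu - us[1]) / sp + 1
  ri <- (vv - vs[1]) / sp + 1
  vapply(seq_along(tt), function(k) {
    r0 <- floor(ri[k]); c0 <- floor(ci[k])
    if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(sl) || c0 + 1 > ncol(sl)) return(NA_real_)
    fr <- ri[k] - r0; fc <- ci[k] - c0
    (1 - fr) * ((1 - fc) * sl[r0, c0] + fc * sl[r0, c0 + 1]) +
      fr * ((1 - fc) * sl[r0 + 1, c0] + fc * sl[r0 + 1, c0 + 1])
  }, numeric(1))
}
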