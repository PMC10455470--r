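# Small 3D geometry helpers shared by the phantom generator, the mesh
# module and the registration module. All coordinates are in mm.

vec_norm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) abort("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rowwise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# An arbitrary pair of unit vectors completing `u` to a right-handed
# orthonormal basis (e1, e2, u).
orthobasis <- function(u) {
  u <- normalize(u)
  helper <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(cross3(helper, u))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2, u = u)
}

# Rotation matrix about a unit axis by angle (Rodrigues).
rotation_about <- function(axis, angle) {
  a <- normalize(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Geodesic angle (deg) between two rotation matrices.
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# Nearest rotation matrix (polar projection, det +1).
nearest_rotation <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    sv$v[, 3] <- -sv$v[, 3]
    R <- sv$u %*% t(sv$v)
  }
  R
}

# Subdivided icosahedron on the unit sphere. `subdivisions = 5` gives
# 20 * 4^5 = 20480 faces, the package's default refinement.
icosphere <- function(subdivisions = 5L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e1 <- f[, c(1, 2), drop = FALSE]
    e2 <- f[, c(2, 3), drop = FALSE]
    e3 <- f[, c(3, 1), drop = FALSE]
    edges <- rbind(e1, e2, e3)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(key)
    mid_idx <- nrow(v) + match(key, uk)
    ue <- edges[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- mid_idx[seq_len(nf)]
    m2 <- mid_idx[nf + seq_len(nf)]
    m3 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m1, m3),
      cbind(f[, 2], m2, m1),
      cbind(f[, 3], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  list(vertices = v, faces = f)
}
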