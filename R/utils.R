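# Small geometry helpers shared across modules. All lengths are in mm.

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_norms <- function(m) sqrt(rowSums(m * m))

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("cannot normalize a zero-length vector")
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Direction on the unit sphere from azimuth (degrees from anterior +y toward
# the subject's right +x) and elevation (degrees above the axial plane).
angles_to_dir <- function(azimuth_deg, elevation_deg) {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

# Signed volumes (mm^3) of tetrahedra given node coordinates and a T x 4 index matrix.
tet_signed_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  rowSums(a * cross3(b, c3)) / 6
}

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
     nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  row_norms(cross3(a, b)) / 2
}
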