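#' Configuration for the synthetic head/orbit phantom
#'
#' Parameters of the layered spherical head phantom used as the synthetic
#' stand-in for an MR-derived head mesh. The head is a sphere of
#' `head_radius` with an outer skin shell, a bone shell underneath, and
#' brain-like tissue inside. Two spherical eyeballs are embedded so that
#' they pierce the bone shell anteriorly (the orbital aperture) and touch
#' the skin layer, preserving the skin-to-eye current-path structure that
#' periocular montages exploit.
#'
#' @param head_radius outer skin radius (mm).
#' @param skin_thickness thickness of the skin shell (mm).
#' @param bone_thickness thickness of the bone shell under the skin (mm).
#' @param eye_radius eyeball radius (mm); the adult eye is about 24 mm in
#'   diameter.
#' @param eye_center centre of the right eyeball, `c(x, y, z)` in mm with
#'   +x toward the subject's right, +y anterior, +z superior. The left eye
#'   is its exact mirror image about the midsagittal plane x = 0.
#' @param orbit_aperture_deg half-angle (degrees) of the conical orbital
#'   aperture cut through the bone shell in front of each eye. The cavity
#'   between eyeball and bone is filled with a conductive aqueous soft
#'   tissue (labelled `csf`), standing in for the orbital contents; bone
#'   does not touch the eyeball equator in a real orbit.
#' @param csf_thickness optional CSF layer under the bone (mm, 0 = absent).
#' @param wm_radius optional white-matter core radius (mm, 0 = absent;
#'   remaining interior is labelled gray matter).
#' @param element_size target edge length of the structured tetrahedral
#'   lattice (mm).
#' @param jitter node jitter amplitude as a fraction of `element_size`;
#'   breaks lattice alignment so that element centroids are in general
#'   position. Midsagittal nodes are never jittered in x so the mesh stays
#'   exactly mirror-symmetric.
#' @param seed integer seed controlling the jitter (recorded in provenance).
#'
#' @return a named list of validated phantom parameters.
#' @export
phantom_config <- function(head_radius = 80, skin_thickness = 4,
                           bone_thickness = 8, eye_radius = 12,
                           eye_center = c(25, 61, 0),
                           orbit_aperture_deg = 16,
                           csf_thickness = 0, wm_radius = 0,
                           element_size = 5, jitter = 0.1, seed = 1L) {
  cfg <- list(
    head_radius = head_radius, skin_thickness = skin_thickness,
    bone_thickness = bone_thickness, eye_radius = eye_radius,
    eye_center = as.numeric(eye_center),
    orbit_aperture_deg = orbit_aperture_deg,
    csf_thickness = csf_thickness,
    wm_radius = wm_radius, element_size = element_size,
    jitter = jitter, seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  pos <- c("head_radius", "skin_thickness", "bone_thickness", "eye_radius",
           "element_size")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      abort(paste0("phantom configuration error: `", k, "` must be a positive number"))
  }
  if (cfg$jitter < 0 || cfg$jitter >= 0.3)
    abort("phantom configuration error: `jitter` must lie in [0, 0.3)")
  if (length(cfg$eye_center) != 3)
    abort("phantom configuration error: `eye_center` must be length 3")
  if (cfg$eye_center[1] <= 0)
    abort("phantom configuration error: the right eye centre must have x > 0")
  r_eye <- sqrt(sum(cfg$eye_center^2))
  if (r_eye + cfg$eye_radius >= cfg$head_radius)
    abort("phantom configuration error: eyeball pokes out of the head (overlapping tissues)")
  if (2 * cfg$eye_center[1] <= 2 * cfg$eye_radius)
    abort("phantom configuration error: left and right eyeballs overlap")
  shells <- cfg$skin_thickness + cfg$bone_thickness + cfg$csf_thickness
  if (shells >= cfg$head_radius)
    abort("phantom configuration error: tissue shells thicker than the head radius")
  # the eye must pierce the bone shell (so an anterior aperture exists) and
  # the aperture must be wider than a mesh cell
  if (r_eye + cfg$eye_radius <= cfg$head_radius - cfg$skin_thickness - cfg$bone_thickness)
    abort("phantom configuration error: eyeball does not reach the bone shell (no orbital aperture)")
  invisible(cfg)
}

# Tissue label for each centroid row of `p` (n x 3), vectorized.
label_tissue <- function(p, cfg) {
  r <- row_norms(p)
  d_right <- row_norms(sweep(p, 2, cfg$eye_center))
  d_left <- row_norms(sweep(p, 2, cfg$eye_center * c(-1, 1, 1)))
  skin_inner <- cfg$head_radius - cfg$skin_thickness
  bone_inner <- skin_inner - cfg$bone_thickness
  csf_inner <- bone_inner - cfg$csf_thickness
  lab <- rep(NA_character_, nrow(p))
  lab[r > cfg$head_radius] <- "outside"
  sel <- is.na(lab) & r > skin_inner
  lab[sel] <- "skin"
  sel <- is.na(lab) & (d_right <= cfg$eye_radius | d_left <= cfg$eye_radius)
  lab[sel] <- "eyeball"
  # conical orbital aperture: the bone-shell region in front of each eye is
  # orbital soft tissue (aqueous, labelled csf), not bone
  ap <- (cfg$orbit_aperture_deg %||% 0) * pi / 180
  in_orbit <- rep(FALSE, nrow(p))
  if (ap > 0) {
    for (ec in list(cfg$eye_center, cfg$eye_center * c(-1, 1, 1))) {
      axis <- ec / sqrt(sum(ec^2))
      cosang <- (p %*% axis) / pmax(r, 1e-12)
      in_orbit <- in_orbit | (cosang > cos(ap))
    }
  }
  sel <- is.na(lab) & r > bone_inner
  lab[sel & in_orbit] <- "csf"
  lab[sel & !in_orbit] <- "bone"
  if (cfg$csf_thickness > 0) {
    sel <- is.na(lab) & r > csf_inner
    lab[sel] <- "csf"
  }
  if (cfg$wm_radius > 0) {
    sel <- is.na(lab) & r <= cfg$wm_radius
    lab[sel] <- "white_matter"
  }
  lab[is.na(lab)] <- "gray_matter"
  lab
}

# The six tetrahedra of the Kuhn subdivision of the unit cube, all sharing
# the main diagonal (0,0,0)-(1,1,1); vertex order fixed at load time so that
# every tetrahedron has positive orientation.
kuhn_offsets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    e <- diag(3)
    v <- rbind(c(0, 0, 0), e[p[1], ], e[p[1], ] + e[p[2], ], c(1, 1, 1))
    # enforce positive signed volume by swapping the last two vertices if needed
    vol <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
    if (vol < 0) v <- v[c(1, 2, 4, 3), ]
    v
  })
})

#' Build the synthetic head/orbit tissue phantom
#'
#' Generates a labelled tetrahedral mesh of the layered spherical head with
#' two embedded eyeballs, by Kuhn subdivision of a structured cubic lattice,
#' seeded node jitter, and centroid-based tissue labelling. The mesh is
#' constructed on the half-space x >= 0 and mirrored, so it is exactly
#' mirror-symmetric about the midsagittal plane.
#'
#' @param config phantom parameters from [phantom_config()].
#' @return an object of class `tissue_phantom`: a list with `nodes` (N x 3,
#'   mm), `tets` (T x 4 node indices), `labels` (tissue per tetrahedron),
#'   `surface` (triangle table with owning tissue, owner element, exterior
#'   flag and eye side), `eye_centers`, `eye_radius` and `provenance`.
#' @export
#' @examples
#' ph <- build_head_phantom(phantom_config(element_size = 10))
#' ph
build_head_phantom <- function(config = phantom_config()) {
  cfg <- validate_phantom_config(config)
  mesh <- lattice_ball_mesh(cfg$head_radius, cfg$element_size, cfg$jitter,
                            cfg$seed, function(p) label_tissue(p, cfg))
  eye_centers <- list(right = cfg$eye_center, left = cfg$eye_center * c(-1, 1, 1))
  surface <- extract_surfaces(mesh$nodes, mesh$tets, mesh$labels, eye_centers)

  structure(list(
    nodes = mesh$nodes,
    tets = mesh$tets,
    labels = mesh$labels,
    volumes = mesh$volumes,
    surface = surface,
    eye_centers = eye_centers,
    eye_radius = cfg$eye_radius,
    provenance = list(config = cfg, seed = cfg$seed),
    mesh_hash = rlang::hash(list(round(mesh$nodes, 9), mesh$tets, mesh$labels))
  ), class = "tissue_phantom")
}

#' Build a homogeneous sphere phantom
#'
#' A single-tissue spherical mesh used to validate the finite-element solver
#' against the analytic conducting-sphere solution. The tissue is labelled
#' `skin` so that electrode pads can be placed on its surface with
#' [place_electrode()]; pass a conductivity map with the desired uniform
#' value for `skin` (and the same value for `gel` to keep the medium
#' homogeneous).
#'
#' @param radius sphere radius (mm).
#' @param element_size lattice edge length (mm).
#' @param jitter node jitter fraction.
#' @param seed jitter seed.
#' @return a `tissue_phantom` with a single tissue and no eyes.
#' @export
build_sphere_phantom <- function(radius = 50, element_size = 4,
                                 jitter = 0.1, seed = 1L) {
  if (radius <= 0 || element_size <= 0) abort("radius and element_size must be positive")
  mesh <- lattice_ball_mesh(radius, element_size, jitter, as.integer(seed),
                            function(p) rep("skin", nrow(p)))
  surface <- extract_surfaces(mesh$nodes, mesh$tets, mesh$labels,
                              list(right = c(radius, 0, 0), left = c(-radius, 0, 0)))
  structure(list(
    nodes = mesh$nodes,
    tets = mesh$tets,
    labels = mesh$labels,
    volumes = mesh$volumes,
    surface = surface,
    eye_centers = NULL,
    eye_radius = NA_real_,
    provenance = list(config = list(head_radius = radius, element_size = element_size,
                                    jitter = jitter, seed = seed, kind = "sphere"),
                      seed = seed),
    mesh_hash = rlang::hash(list(round(mesh$nodes, 9), mesh$tets, mesh$labels))
  ), class = "tissue_phantom")
}

# Structured, midsagittally mirror-symmetric tetrahedral mesh of the ball of
# the given radius: Kuhn subdivision of a cubic lattice on the half-cube
# x >= 0, seeded jitter (tangential only on the cube surface, zero x-jitter
# on the midplane), the classical elliptical cube-to-ball mapping (which
# carries the cube surface exactly onto the sphere, so the mesh boundary is
# conforming rather than a voxel staircase), centroid labelling, then
# mirroring with an orientation fix.
lattice_ball_mesh <- function(radius, h, jitter, seed, label_fun) {
  m <- max(2L, ceiling(radius / h)) # cells per half-axis in cube space

  # half-lattice nodes in cube coordinates [0,1] x [-1,1]^2
  ix <- 0:m
  iyz <- -m:m
  grid <- expand.grid(ix = ix, iy = iyz, iz = iyz, KEEP.OUT.ATTRS = FALSE)
  nx <- length(ix); nyz <- length(iyz)
  nid <- function(i, j, k) (i + 1L) + nx * ((j + m) + nyz * (k + m))

  p <- cbind(grid$ix, grid$iy, grid$iz) / m
  on_surface <- grid$ix == m | abs(grid$iy) == m | abs(grid$iz) == m
  on_midplane <- grid$ix == 0L

  # tetrahedra for every lattice cube in the half-space
  cubes <- expand.grid(i = 0:(m - 1L), j = (-m):(m - 1L), k = (-m):(m - 1L),
                       KEEP.OUT.ATTRS = FALSE)
  tets <- do.call(rbind, lapply(kuhn_offsets, function(off) {
    cbind(
      nid(cubes$i + off[1, 1], cubes$j + off[1, 2], cubes$k + off[1, 3]),
      nid(cubes$i + off[2, 1], cubes$j + off[2, 2], cubes$k + off[2, 3]),
      nid(cubes$i + off[3, 1], cubes$j + off[3, 2], cubes$k + off[3, 3]),
      nid(cubes$i + off[4, 1], cubes$j + off[4, 2], cubes$k + off[4, 3])
    )
  }))
  storage.mode(tets) <- "integer"

  nodes <- cube_to_ball(p) * radius
  nodes <- untangle_mesh(nodes, tets, on_surface, on_midplane, radius)
  nodes <- jitter_nodes(nodes, tets, jitter, seed, on_surface, on_midplane, radius)
  labels <- label_fun(tet_centroids(nodes, tets))

  # mirror about x = 0: midplane nodes are shared, mirrored tets have two
  # vertices swapped to restore positive orientation
  on_plane <- abs(nodes[, 1]) < 1e-12
  mir <- integer(nrow(nodes))
  mir[on_plane] <- which(on_plane)
  mir[!on_plane] <- nrow(nodes) + seq_len(sum(!on_plane))
  nodes <- rbind(nodes, nodes[!on_plane, , drop = FALSE] * rep(c(-1, 1, 1), each = sum(!on_plane)))
  tets_m <- matrix(mir[tets], ncol = 4)[, c(1, 2, 4, 3), drop = FALSE]
  tets <- rbind(tets, tets_m)
  labels <- c(labels, labels)

  vols <- tet_signed_volumes(nodes, tets)
  if (any(vols <= 0))
    abort(paste0("phantom configuration error: ", sum(vols <= 0),
                 " tetrahedra with non-positive volume (jitter too large?)"))

  list(nodes = nodes, tets = tets, labels = labels, volumes = vols)
}

# Local Laplacian untangling: the cube-to-ball mapping can leave a handful
# of marginally inverted cells at the eight cube corners. Nodes of
# non-positive tetrahedra are relaxed toward the centroid of their star
# neighbours (sphere-surface nodes slide on the sphere, midplane nodes stay
# on the plane) until all volumes are positive.
untangle_mesh <- function(nodes, tets, on_surface, on_midplane, radius,
                          max_iter = 50L) {
  v <- tet_signed_volumes(nodes, tets)
  if (all(v > 1e-9)) return(nodes)
  node_tets <- split(rep(seq_len(nrow(tets)), 4), as.vector(tets))
  for (it in seq_len(max_iter)) {
    bad <- which(v <= 1e-9)
    if (length(bad) == 0) return(nodes)
    bn <- unique(as.vector(tets[bad, , drop = FALSE]))
    for (b in bn) {
      inc <- node_tets[[as.character(b)]]
      nbrs <- setdiff(unique(as.vector(tets[inc, , drop = FALSE])), b)
      target <- colMeans(nodes[nbrs, , drop = FALSE])
      if (on_surface[b]) target <- target * (radius / sqrt(sum(target^2)))
      if (on_midplane[b]) target[1] <- 0
      nodes[b, ] <- 0.5 * nodes[b, ] + 0.5 * target
    }
    v <- tet_signed_volumes(nodes, tets)
  }
  abort("phantom configuration error: could not untangle the mapped lattice mesh")
}

# Seeded node jitter in physical space, scaled per node by the minimum
# incident edge length (the cube-to-ball mapping compresses cells near the
# cube diagonals). Sphere-surface nodes are jittered tangentially and
# re-normalized so the boundary stays exactly spherical; midplane nodes keep
# x = 0. A damping pass halves the jitter of any node involved in a
# non-positive tetrahedron, keeping the mesh valid deterministically.
jitter_nodes <- function(nodes, tets, jitter, seed, on_surface, on_midplane, radius) {
  if (jitter <= 0) return(nodes)
  # per-node scale: shortest edge of any incident tetrahedron
  tet_min_edge <- rep(Inf, nrow(tets))
  combs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (cb in combs) {
    e <- row_norms(nodes[tets[, cb[1]], , drop = FALSE] -
                     nodes[tets[, cb[2]], , drop = FALSE])
    tet_min_edge <- pmin(tet_min_edge, e)
  }
  scale <- rep(Inf, nrow(nodes))
  for (k in 1:4) {
    agg <- tapply(tet_min_edge, tets[, k], min)
    idx <- as.integer(names(agg))
    scale[idx] <- pmin(scale[idx], as.numeric(agg))
  }
  scale[!is.finite(scale)] <- 0

  set.seed(seed)
  J <- matrix(runif(3L * nrow(nodes), -1, 1), ncol = 3) * (jitter * scale)
  if (any(on_surface)) {
    nh <- nodes[on_surface, , drop = FALSE] / radius
    J[on_surface, ] <- J[on_surface, , drop = FALSE] -
      nh * rowSums(J[on_surface, , drop = FALSE] * nh)
  }
  J[on_midplane, 1] <- 0

  for (it in 1:8) {
    prop <- nodes + J
    if (any(on_surface)) {
      ps <- prop[on_surface, , drop = FALSE]
      prop[on_surface, ] <- ps * (radius / row_norms(ps))
    }
    vols <- tet_signed_volumes(prop, tets)
    bad <- vols <= 1e-9
    if (!any(bad)) return(prop)
    bad_nodes <- unique(as.vector(tets[bad, , drop = FALSE]))
    J[bad_nodes, ] <- J[bad_nodes, , drop = FALSE] / 2
  }
  nodes # all-else-failing fallback: unjittered (still a valid mesh)
}

# Elliptical mapping of the solid cube [-1,1]^3 onto the unit ball; the cube
# surface maps exactly onto the unit sphere.
cube_to_ball <- function(p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  cbind(
    x * sqrt(pmax(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3, 0)),
    y * sqrt(pmax(1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3, 0)),
    z * sqrt(pmax(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3, 0))
  )
}

# Face table of the labelled mesh: exterior boundary faces plus
# tissue-interface faces (one row per owning side).
extract_surfaces <- function(nodes, tets, labels, eye_centers) {
  f1 <- tets[, c(2, 3, 4)]; f2 <- tets[, c(1, 3, 4)]
  f3 <- tets[, c(1, 2, 4)]; f4 <- tets[, c(1, 2, 3)]
  faces <- rbind(f1, f2, f3, f4)
  owner <- rep(seq_len(nrow(tets)), 4)
  a <- faces[, 1]; b <- faces[, 2]; c3 <- faces[, 3]
  lo <- pmin(a, b, c3); hi <- pmax(a, b, c3); mid <- a + b + c3 - lo - hi
  ord <- order(lo, mid, hi)
  lo <- lo[ord]; mid <- mid[ord]; hi <- hi[ord]; owner <- owner[ord]
  same_as_prev <- c(FALSE, lo[-1] == lo[-length(lo)] &
                      mid[-1] == mid[-length(mid)] & hi[-1] == hi[-length(hi)])
  # faces appear once (boundary) or twice (internal)
  first_of_pair <- same_as_prev & !c(FALSE, same_as_prev[-length(same_as_prev)])
  is_single <- !same_as_prev & !c(same_as_prev[-1], FALSE)

  rows <- list()
  if (any(is_single)) {
    rows$ext <- data.frame(
      n1 = lo[is_single], n2 = mid[is_single], n3 = hi[is_single],
      tet = owner[is_single], label = labels[owner[is_single]],
      exterior = TRUE, stringsAsFactors = FALSE
    )
  }
  if (any(first_of_pair)) {
    i2 <- which(first_of_pair)
    i1 <- i2 - 1L
    t1 <- owner[i1]; t2 <- owner[i2]
    diff_lab <- labels[t1] != labels[t2]
    if (any(diff_lab)) {
      i1 <- i1[diff_lab]; i2 <- i2[diff_lab]
      t1 <- t1[diff_lab]; t2 <- t2[diff_lab]
      rows$int <- data.frame(
        n1 = c(lo[i1], lo[i2]), n2 = c(mid[i1], mid[i2]), n3 = c(hi[i1], hi[i2]),
        tet = c(t1, t2), label = c(labels[t1], labels[t2]),
        exterior = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  surf <- do.call(rbind, rows)
  rownames(surf) <- NULL
  # eye side for eyeball-owned faces
  surf$eye <- NA_character_
  is_eye <- surf$label == "eyeball"
  if (any(is_eye)) {
    cc <- (nodes[surf$n1[is_eye], , drop = FALSE] +
             nodes[surf$n2[is_eye], , drop = FALSE] +
             nodes[surf$n3[is_eye], , drop = FALSE]) / 3
    dr <- row_norms(sweep(cc, 2, eye_centers$right))
    dl <- row_norms(sweep(cc, 2, eye_centers$left))
    surf$eye[is_eye] <- ifelse(dr <= dl, "right", "left")
  }
  surf
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cfg <- x$provenance$config
  cat("<tissue_phantom>\n")
  cat(sprintf("  nodes: %d, tetrahedra: %d (element size %.1f mm, jitter %.2f, seed %d)\n",
              nrow(x$nodes), nrow(x$tets), cfg$element_size, cfg$jitter, cfg$seed))
  tab <- table(x$labels)
  cat("  tissues:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  eyes: radius %.1f mm, right centre (%.1f, %.1f, %.1f) mm\n",
              x$eye_radius, x$eye_centers$right[1], x$eye_centers$right[2],
              x$eye_centers$right[3]))
  invisible(x)
}

#' Summed tissue volumes of a phantom
#'
#' @param phantom a `tissue_phantom`.
#' @return tibble with one row per tissue label and its total volume in mm^3.
#' @export
phantom_tissue_volumes <- function(phantom) {
  v <- tapply(phantom$volumes, phantom$labels, sum)
  tibble(tissue = names(v), volume_mm3 = as.numeric(v))
}
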