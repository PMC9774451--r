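#' Named skin sites of the periocular montage catalog
#'
#' Electrode centre positions are specified as (azimuth, elevation) angles on
#' the phantom's skin sphere: azimuth in degrees from the anterior direction
#' (+y) toward the subject's right (+x), elevation in degrees above the axial
#' plane. Active pads sit on the lower orbital rim (temporal / central /
#' nasal of each eye), return pads on the cheeks. Left-side sites are exact
#' mirrors of their right-side counterparts.
#'
#' @return tibble with columns `site`, `azimuth_deg`, `elevation_deg`.
#' @export
electrode_sites <- function() {
  right <- tibble::tribble(
    ~site, ~azimuth_deg, ~elevation_deg,
    "temporal_active_right",     40, -14,
    "temporal_active_low_right", 44, -24, # revised temporal pad, moved away from the upper eye
    "central_active_right",      22, -30,
    "nasal_active_right",         2, -26,
    "temporal_return_right",     22, -56,
    "central_return_right",      10, -64,
    "nasal_return_right",        58, -54,
    # the failing close-contact arrangement: two active pads that cover the
    # orbital aperture almost identically, and one shared lower-cheek return,
    # so the two current paths cross at the lower electrode
    "overlap_active_b_right",    31, -18,
    "overlap_active_d_right",    27, -20,
    "overlap_return_right",      29, -58
  )
  left <- right
  left$site <- sub("_right$", "_left", left$site)
  left$azimuth_deg <- -left$azimuth_deg
  dplyr::bind_rows(right, left)
}

resolve_site <- function(center_spec) {
  if (is.character(center_spec) && length(center_spec) == 1) {
    st <- electrode_sites()
    row <- st[st$site == center_spec, ]
    if (nrow(row) != 1)
      abort(paste0("placement error: unknown electrode site `", center_spec, "`"))
    return(angles_to_dir(row$azimuth_deg, row$elevation_deg))
  }
  if (is.numeric(center_spec) && length(center_spec) == 2)
    return(angles_to_dir(center_spec[1], center_spec[2]))
  if (is.numeric(center_spec) && length(center_spec) == 3)
    return(unit(center_spec))
  abort("placement error: `center_spec` must be a site name, c(azimuth, elevation) or a direction vector")
}

# Local tangent frame of a pad centred on direction u; e1 points along
# increasing azimuth, e2 along increasing elevation.
pad_frame <- function(u) {
  zax <- c(0, 0, 1)
  if (abs(sum(u * zax)) > 0.999)
    abort("placement error: electrode centred at a pole of the head sphere")
  e1 <- unit(c(zax[2] * u[3] - zax[3] * u[2],
               zax[3] * u[1] - zax[1] * u[3],
               zax[1] * u[2] - zax[2] * u[1]))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Geodesic square-footprint membership for point directions `ph` (n x 3 unit
# rows): TRUE where the point lies within the L x L pad centred on u.
in_footprint <- function(ph, u, edge_length, head_radius) {
  ct <- clamp(ph %*% u, -1, 1)
  theta <- acos(ct)
  tang <- ph - outer(as.vector(ct), u)
  tn <- row_norms(tang)
  tn[tn == 0] <- 1
  tang <- tang / tn
  fr <- pad_frame(u)
  a <- head_radius * theta * (tang %*% fr$e1)
  b <- head_radius * theta * (tang %*% fr$e2)
  half <- edge_length / 2
  as.vector(abs(a) <= half & abs(b) <= half)
}

#' Place a square electrode pad on the phantom skin
#'
#' Projects a square pad of the given edge length onto the skin surface
#' around a centre site and collects the exterior skin nodes inside the
#' geodesic footprint (the pad contact) together with the skin elements
#' under the footprint (the gel volume).
#'
#' @param phantom a `tissue_phantom`.
#' @param center_spec a site name from [electrode_sites()], `c(azimuth,
#'   elevation)` in degrees, or a 3-vector direction.
#' @param edge_length pad edge (mm); the reference stimulator pad is
#'   42 mm x 42 mm.
#' @param current drive current in mA (signed; positive = anode).
#' @param name optional label.
#' @return an `electrode_patch`: node ids of the skin contact, gel element
#'   ids, contact area (mm^2), centre direction and pad frame.
#' @export
place_electrode <- function(phantom, center_spec, edge_length = 42,
                            current = 1, name = NULL) {
  if (!is.numeric(edge_length) || edge_length <= 0)
    abort("placement error: `edge_length` must be positive")
  u <- resolve_site(center_spec)
  cfg <- phantom$provenance$config
  surf <- phantom$surface
  ext_skin <- surf[surf$exterior & surf$label == "skin", , drop = FALSE]
  if (nrow(ext_skin) == 0) abort("placement error: phantom has no exterior skin surface")
  skin_nodes <- sort(unique(c(ext_skin$n1, ext_skin$n2, ext_skin$n3)))
  ph_dir <- phantom$nodes[skin_nodes, , drop = FALSE]
  ph_dir <- ph_dir / row_norms(ph_dir)
  inside <- in_footprint(ph_dir, u, edge_length, cfg$head_radius)
  patch_nodes <- skin_nodes[inside]
  if (length(patch_nodes) == 0)
    abort("resolution error: electrode footprint covers no skin nodes (mesh too coarse or pad too small)")

  # contact area: exterior skin faces whose centroid direction lies inside the
  # footprint, measured on their radial projection onto the head sphere (the
  # footprint as seen on the skin, free of the voxel-staircase inflation)
  fc <- (phantom$nodes[ext_skin$n1, , drop = FALSE] +
           phantom$nodes[ext_skin$n2, , drop = FALSE] +
           phantom$nodes[ext_skin$n3, , drop = FALSE]) / 3
  face_in <- in_footprint(fc / row_norms(fc), u, edge_length, cfg$head_radius)
  proj <- function(idx) {
    p <- phantom$nodes[idx, , drop = FALSE]
    p * (cfg$head_radius / row_norms(p))
  }
  sel <- which(face_in)
  pn <- rbind(proj(ext_skin$n1[sel]), proj(ext_skin$n2[sel]), proj(ext_skin$n3[sel]))
  k <- length(sel)
  area <- sum(triangle_areas(pn, cbind(seq_len(k), k + seq_len(k), 2L * k + seq_len(k))))

  # gel: skin elements whose centroid falls under the footprint
  skin_el <- which(phantom$labels == "skin")
  cent <- tet_centroids(phantom$nodes, phantom$tets[skin_el, , drop = FALSE])
  cdir <- cent / row_norms(cent)
  gel <- skin_el[in_footprint(cdir, u, edge_length, cfg$head_radius)]

  structure(list(
    name = name %||% if (is.character(center_spec)) center_spec else "custom",
    center_dir = u, edge_length = edge_length, current = current,
    nodes = patch_nodes, gel_elements = gel, area = area,
    contact_faces = which(surf$exterior & surf$label == "skin")[face_in]
  ), class = "electrode_patch")
}

#' @export
print.electrode_patch <- function(x, ...) {
  cat(sprintf("<electrode_patch> %s: %.0f mm pad, %d skin nodes, area %.0f mm^2, %g mA\n",
              x$name, x$edge_length, length(x$nodes), x$area, x$current))
  invisible(x)
}

#' Overlap between two electrode patches
#'
#' @param p1,p2 `electrode_patch` objects on the same phantom.
#' @return tibble with the shared node count and the shared fraction of the
#'   smaller patch.
#' @export
patch_overlap <- function(p1, p2) {
  shared <- intersect(p1$nodes, p2$nodes)
  tibble(
    patch1 = p1$name, patch2 = p2$name,
    n_shared = length(shared),
    fraction_smaller = length(shared) / min(length(p1$nodes), length(p2$nodes))
  )
}

# ---- montage catalog ---------------------------------------------------

# Pair letters: A temporal-right, B temporal-left, C central-right,
# D central-left, E nasal (active near the nose). Each pair is an active pad
# on the lower orbital rim plus a cheek return pad.
pair_defs <- function() {
  list(
    A = list(active = "temporal_active_right", ret = "temporal_return_right",
             eye = "right", region = "temporal"),
    A_rev = list(active = "temporal_active_low_right", ret = "temporal_return_right",
                 eye = "right", region = "temporal"),
    B = list(active = "temporal_active_left", ret = "temporal_return_left",
             eye = "left", region = "temporal"),
    C = list(active = "central_active_right", ret = "central_return_right",
             eye = "right", region = "central"),
    D = list(active = "central_active_left", ret = "central_return_left",
             eye = "left", region = "central"),
    # the close-contact left-eye arrangement whose current paths cross at the
    # shared lower electrode
    B_ov = list(active = "overlap_active_b_left", ret = "overlap_return_left",
                eye = "left", region = "temporal"),
    D_ov = list(active = "overlap_active_d_left", ret = "overlap_return_left",
                eye = "left", region = "central"),
    E_left = list(active = "nasal_active_left", ret = "nasal_return_right",
                  eye = "left", region = "nasal"),
    # the nasal-right pair's return is moved to the opposite cheek because its
    # catalog position coincides with the temporal-right return
    E_right = list(active = "nasal_active_right", ret = "nasal_return_left",
                   eye = "right", region = "nasal")
  )
}

montage_table <- function() {
  list(
    "A+B" = list(pairs = c("A", "B"), currents = c(1, 1), aliases = c("electrode_1", "1")),
    "B+C" = list(pairs = c("B", "C"), currents = c(1, 1), aliases = c("electrode_2", "2")),
    "A+D" = list(pairs = c("A", "D"), currents = c(1, 1), aliases = c("electrode_3", "3")),
    "B+D" = list(pairs = c("B_ov", "D_ov"), currents = c(1, 1), aliases = c("electrode_4", "4")),
    "A+C" = list(pairs = c("A", "C"), currents = c(1, 1), aliases = c("electrode_5", "5")),
    "B+E" = list(pairs = c("B", "E_left"), currents = c(1, 1), aliases = c("electrode_6", "6")),
    "A+E" = list(pairs = c("A", "E_right"), currents = c(1, 1), aliases = c("electrode_7", "7")),
    "B+E_boost" = list(pairs = c("B", "E_left"), currents = c(1, 1.5),
                       aliases = c("electrode_6_boost", "6_boost")),
    "A+E_boost" = list(pairs = c("A", "E_right"), currents = c(1, 1.5),
                       aliases = c("electrode_7_boost", "7_boost")),
    "B+E_corrected" = list(pairs = c("B", "E_left"), currents = c(0.8, 1.5),
                           aliases = c("electrode_6_corrected", "6_corrected")),
    "A+E_corrected" = list(pairs = c("A", "E_right"), currents = c(0.8, 1.5),
                           aliases = c("electrode_7_corrected", "7_corrected")),
    "A+B_revised" = list(pairs = c("A_rev", "B"), currents = c(1, 1),
                         aliases = c("revised_1", "electrode_1_revised")),
    "A+D_revised" = list(pairs = c("A_rev", "D"), currents = c(1, 1),
                         aliases = c("revised_3", "electrode_3_revised")),
    "B+D_revised" = list(pairs = c("B", "D"), currents = c(1, 1),
                         aliases = c("revised_4", "electrode_4_revised")),
    "A+C_revised" = list(pairs = c("A_rev", "C"), currents = c(1, 1),
                         aliases = c("revised_5", "electrode_5_revised")),
    "A+E_revised" = list(pairs = c("A_rev", "E_right"), currents = c(0.8, 1.5),
                         aliases = c("revised_7", "electrode_7_revised"))
  )
}

#' Montage catalog
#'
#' Returns a montage definition by name. The catalog mirrors the studied
#' two-pair arrangements: pairs A-E target the temporal/central/nasal lower
#' ocular surface of each eye (A temporal-right, B temporal-left, C
#' central-right, D central-left, E nasal), combined as A+B, B+C, A+D, B+D,
#' A+C, B+E and A+E, plus revised placements and the boosted/corrected
#' current settings for the nasal arrangements (1 & 1.5 mA and 0.8 & 1.5 mA).
#' Electrode-number aliases `electrode_1` .. `electrode_7` (and `"1"` ..
#' `"7"`) map to the pair combinations in that order.
#'
#' @param name montage name, e.g. `"A+C"`, `"electrode_5"`,
#'   `"B+E_corrected"`, `"revised_4"`.
#' @param currents optional length-2 override of the pair currents in mA.
#' @return a `montage`: name, pair tibble (pair letter, active site, return
#'   site, current, target eye/region) and phase options.
#' @export
#' @examples
#' montage_catalog("A+C")
montage_catalog <- function(name, currents = NULL) {
  tab <- montage_table()
  canon <- NULL
  if (name %in% names(tab)) canon <- name
  else {
    for (k in names(tab)) if (name %in% tab[[k]]$aliases) { canon <- k; break }
  }
  if (is.null(canon))
    abort(paste0("catalog error: unknown montage `", name, "`; known: ",
                 paste(names(tab), collapse = ", ")))
  def <- tab[[canon]]
  if (!is.null(currents)) {
    if (length(currents) != length(def$pairs) || any(currents <= 0))
      abort("catalog error: `currents` must be positive, one per pair")
    def$currents <- currents
  }
  pd <- pair_defs()
  pairs <- dplyr::bind_rows(lapply(seq_along(def$pairs), function(i) {
    p <- pd[[def$pairs[i]]]
    tibble(pair = def$pairs[i], active_site = p$active, return_site = p$ret,
           current = def$currents[i], eye = p$eye, region = p$region)
  }))
  structure(list(
    name = canon,
    pairs = pairs,
    phase_options = c("same", "anti"),
    target_regions = pairs[, c("eye", "region", "pair")]
  ), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %s (%d pairs)\n", x$name, nrow(x$pairs)))
  print(as.data.frame(x$pairs), row.names = FALSE)
  invisible(x)
}

#' Place all pads of a montage on a phantom
#'
#' Places the active and return pad of every pair and enforces the montage
#' invariants: within each pair the two pads must cover disjoint skin node
#' sets (the injected anode current equals the extracted cathode current by
#' construction of the solver drive).
#'
#' @param phantom a `tissue_phantom`.
#' @param montage a `montage` from [montage_catalog()].
#' @param edge_length pad edge length in mm.
#' @return list of pairs, each with `anode`, `cathode` (`electrode_patch`),
#'   `current`, and the target eye/region.
#' @export
place_montage <- function(phantom, montage, edge_length = 42) {
  lapply(seq_len(nrow(montage$pairs)), function(i) {
    row <- montage$pairs[i, ]
    an <- place_electrode(phantom, row$active_site, edge_length, current = row$current)
    ca <- place_electrode(phantom, row$return_site, edge_length, current = -row$current)
    if (length(intersect(an$nodes, ca$nodes)) > 0)
      abort(paste0("placement error: pads of pair ", row$pair,
                   " overlap on the skin (", row$active_site, " / ", row$return_site, ")"))
    list(pair = row$pair, anode = an, cathode = ca, current = row$current,
         eye = row$eye, region = row$region)
  })
}
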