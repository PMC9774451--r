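phase_signs_for <- function(phase, n_pairs) {
  switch(phase,
    same = rep(1, n_pairs),
    anti = rep(c(1, -1), length.out = n_pairs),
    abort(paste0("unknown phase option `", phase, "` (use \"same\" or \"anti\")"))
  )
}

#' Run a montage under same-phase and anti-phase drives and score locality
#'
#' The full study pipeline for one electrode arrangement: every pair is
#' solved once (with all pads' gel volumes present), the per-pair solutions
#' are superposed with the phase signs of each requested phase option, the
#' eyeball surface fields are unwrapped and gridded, and a locality report
#' is produced for every target region. The recommended phase maximizes the
#' minimum `delta_adjacent` over the montage's target regions (the montage
#' is only as local as its worst target).
#'
#' @param phantom a `tissue_phantom`.
#' @param montage a `montage` or a catalog name.
#' @param sigma conductivity map.
#' @param phases subset of `c("same", "anti")`.
#' @param grid_resolution_deg evaluation grid cell size (degrees).
#' @param edge_length pad edge (mm).
#' @return a `phase_comparison`: tibble of locality reports per phase and
#'   region, the recommended phase, currents, and provenance.
#' @export
run_arrangement <- function(phantom, montage, sigma = conductivity_map(),
                            phases = c("same", "anti"),
                            grid_resolution_deg = 1, edge_length = 42) {
  if (is.character(montage)) montage <- montage_catalog(montage)
  if (nrow(montage$target_regions) == 0)
    abort(paste0("montage `", montage$name, "` has no target regions"))
  placed <- place_montage(phantom, montage, edge_length)
  all_pads <- unlist(lapply(placed, function(p) list(p$anode, p$cathode)),
                     recursive = FALSE)
  sols <- lapply(placed, function(p)
    solve_pair(phantom, p, sigma = sigma, gel_patches = all_pads))

  eyes <- unique(montage$target_regions$eye)
  reports <- dplyr::bind_rows(lapply(phases, function(ph) {
    signs <- phase_signs_for(ph, length(sols))
    comb <- if (length(sols) == 1) sols[[1]] else superpose(sols, signs)
    grids <- lapply(setNames(eyes, eyes), function(e) {
      interpolate_grid(extract_eye_surface(phantom, comb, e),
                       resolution_deg = grid_resolution_deg)
    })
    dplyr::bind_rows(lapply(seq_len(nrow(montage$target_regions)), function(i) {
      tr <- montage$target_regions[i, ]
      fellow <- montage$target_regions
      fellow <- fellow$region[fellow$eye == tr$eye & fellow$region != tr$region]
      rep <- locality_report(grids[[tr$eye]], tr$region, eye = tr$eye,
                             exclude_adjacent = fellow)
      rep$phase <- ph
      rep$pair <- tr$pair
      rep
    }))
  }))

  by_phase <- vapply(phases, function(ph) {
    d <- reports$delta_adjacent[reports$phase == ph]
    if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
  }, numeric(1))
  recommended <- if (all(is.na(by_phase))) phases[1] else phases[which.max(by_phase)]

  structure(list(
    montage = montage$name,
    currents = montage$pairs$current,
    phases = phases,
    reports = reports,
    min_delta_adjacent = by_phase,
    recommended_phase = recommended,
    solutions = sols,
    provenance = list(
      mesh_hash = phantom$mesh_hash,
      phantom_config = phantom$provenance$config,
      grid_resolution_deg = grid_resolution_deg,
      solver_residuals = vapply(sols, function(s) s$residual, numeric(1))
    )
  ), class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("<phase_comparison> montage %s (currents %s mA)\n",
              x$montage, paste(x$currents, collapse = " & ")))
  cat(sprintf("  recommended phase: %s (min delta_adjacent: %s)\n",
              x$recommended_phase,
              paste(sprintf("%s=%.3f", names(x$min_delta_adjacent),
                            x$min_delta_adjacent), collapse = ", ")))
  print(as.data.frame(x$reports[, c("phase", "eye", "region", "max_in",
                                    "max_upper", "max_adjacent",
                                    "delta_upper", "delta_adjacent")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Locality reports over a grid of pair currents
#'
#' By linearity of the conduction problem each pair is solved once at 1 mA
#' and rescaled, so sweeping currents costs one superposition and
#' evaluation per grid point.
#'
#' @param phantom a `tissue_phantom`.
#' @param montage a `montage` or catalog name.
#' @param sigma conductivity map.
#' @param current_grid data frame (or matrix) with one column per pair, one
#'   row per current combination, in mA.
#' @param phase `"same"` or `"anti"`.
#' @param grid_resolution_deg evaluation grid cell size (degrees).
#' @param edge_length pad edge (mm).
#' @return tibble of locality reports with the current combination columns
#'   prepended.
#' @export
current_sweep <- function(phantom, montage, sigma = conductivity_map(),
                          current_grid, phase = "same",
                          grid_resolution_deg = 1, edge_length = 42) {
  if (is.character(montage)) montage <- montage_catalog(montage)
  cg <- as.matrix(current_grid)
  if (ncol(cg) != nrow(montage$pairs))
    abort("current_grid needs one column per montage pair")
  if (any(cg <= 0)) abort("currents must be positive")
  placed <- place_montage(phantom, montage, edge_length)
  all_pads <- unlist(lapply(placed, function(p) list(p$anode, p$cathode)),
                     recursive = FALSE)
  base <- lapply(placed, function(p) {
    p$current <- 1
    solve_pair(phantom, p, sigma = sigma, gel_patches = all_pads)
  })
  signs <- phase_signs_for(phase, length(base))
  eyes <- unique(montage$target_regions$eye)

  dplyr::bind_rows(lapply(seq_len(nrow(cg)), function(k) {
    scaled <- lapply(seq_along(base), function(i) rescale_solution(base[[i]], cg[k, i]))
    comb <- if (length(scaled) == 1) scaled[[1]] else superpose(scaled, signs)
    grids <- lapply(setNames(eyes, eyes), function(e) {
      interpolate_grid(extract_eye_surface(phantom, comb, e),
                       resolution_deg = grid_resolution_deg)
    })
    dplyr::bind_rows(lapply(seq_len(nrow(montage$target_regions)), function(i) {
      tr <- montage$target_regions[i, ]
      fellow <- montage$target_regions
      fellow <- fellow$region[fellow$eye == tr$eye & fellow$region != tr$region]
      rep <- locality_report(grids[[tr$eye]], tr$region, eye = tr$eye,
                             exclude_adjacent = fellow)
      rep$phase <- phase
      rep$pair <- tr$pair
      for (j in rev(seq_len(ncol(cg))))
        rep <- tibble::add_column(rep, !!paste0("current", j) := cg[k, j],
                                  .before = 1)
      rep
    }))
  }))
}

# Closest points between two 3D segments (standard clamped quadratic).
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  b <- sum(d1 * d2); c <- sum(d1 * r)
  denom <- a * e - b * b
  s <- if (denom > 1e-12) clamp((b * f - c * e) / denom, 0, 1) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- clamp(-c / a, 0, 1) }
  else if (t > 1) { t <- 1; s <- clamp((b - c) / a, 0, 1) }
  cp1 <- p1 + s * d1; cp2 <- p2 + t * d2
  list(distance = sqrt(sum((cp1 - cp2)^2)), point = (cp1 + cp2) / 2)
}

#' Diagnose current-path crossings between electrode pairs
#'
#' Heuristic for anti-phase cancellation risk: for every two pairs of a
#' montage, the straight-line chords between their pad centres are
#' compared; if the chords pass within `clearance` of each other and the
#' closest-approach point lies under a pad footprint, the montage is prone
#' to current-path cancellation under anti-phase drive (the two pairs push
#' opposing currents through the same patch of tissue).
#'
#' @param phantom a `tissue_phantom`.
#' @param montage a `montage` or catalog name.
#' @param clearance crossing distance threshold (mm).
#' @param edge_length pad edge (mm).
#' @return tibble with one row per pair-of-pairs: chord distance, crossing
#'   flag, and the pad (if any) whose footprint contains the crossing
#'   point. Zero rows for a single-pair montage.
#' @export
cancellation_diagnostic <- function(phantom, montage, clearance = 10,
                                    edge_length = 42) {
  if (is.character(montage)) montage <- montage_catalog(montage)
  placed <- place_montage(phantom, montage, edge_length)
  if (length(placed) < 2) {
    return(tibble(pair1 = character(), pair2 = character(),
                  distance_mm = numeric(), crossing = logical(),
                  within_patch = character()))
  }
  R <- phantom$provenance$config$head_radius
  chord <- function(p) list(a = p$anode$center_dir * R, b = p$cathode$center_dir * R)
  combs <- utils::combn(length(placed), 2)
  dplyr::bind_rows(lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    ci <- chord(placed[[i]]); cj <- chord(placed[[j]])
    sd <- segment_distance(ci$a, ci$b, cj$a, cj$b)
    pads <- list(placed[[i]]$anode, placed[[i]]$cathode,
                 placed[[j]]$anode, placed[[j]]$cathode)
    hit <- NA_character_
    if (sd$distance < clearance) {
      pdir <- matrix(sd$point / sqrt(sum(sd$point^2)), 1, 3)
      for (pad in pads) {
        if (in_footprint(pdir, pad$center_dir, pad$edge_length, R)) {
          hit <- pad$name; break
        }
      }
    }
    tibble(pair1 = placed[[i]]$pair, pair2 = placed[[j]]$pair,
           distance_mm = sd$distance,
           crossing = sd$distance < clearance,
           within_patch = hit)
  }))
}
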