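#' Spherical frame of an eye
#'
#' Orthonormal frame used to unwrap an eyeball surface into longitude and
#' latitude. Longitude 0 points at the temporal edge of the anterior
#' hemisphere (toward the ear), longitude pi/2 is anterior (out of the
#' face), so the anterior half of the eye maps to longitudes `[0, pi]` and
#' the posterior half to negative longitudes. Latitude 0 is the horizontal
#' meridian, positive upward. The left-eye frame is the mirror image of the
#' right-eye frame, so left/right longitudes are directly comparable.
#'
#' @param eye `"right"` or `"left"`.
#' @return list with unit vectors `temporal`, `anterior`, `up`.
#' @export
eye_frame <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (eye == "right") {
    list(temporal = c(1, 0, 0), anterior = c(0, 1, 0), up = c(0, 0, 1))
  } else {
    list(temporal = c(-1, 0, 0), anterior = c(0, 1, 0), up = c(0, 0, 1))
  }
}

#' Longitude/latitude of points on an eyeball surface
#'
#' Maps points to spherical coordinates about an eye centre: longitude in
#' `[-pi, pi)` measured from the frame's temporal axis toward the anterior
#' axis, latitude in `[-pi/2, pi/2]` positive toward the frame's up axis.
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates (mm).
#' @param eye_center eye centre (mm).
#' @param frame an [eye_frame()] (or an eye name).
#' @return tibble with columns `longitude`, `latitude` (radians).
#' @export
to_spherical <- function(points, eye_center, frame = "right") {
  if (is.character(frame)) frame <- eye_frame(frame)
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  d <- sweep(p, 2, eye_center)
  r <- row_norms(d)
  if (any(r < 1e-12)) abort("cannot unwrap a point at the eye centre (zero-length vector)")
  u <- d / r
  lon <- atan2(u %*% frame$anterior, u %*% frame$temporal)
  lon <- ((lon + pi) %% (2 * pi)) - pi
  lat <- asin(clamp(u %*% frame$up, -1, 1))
  tibble(longitude = as.numeric(lon), latitude = as.numeric(lat))
}

#' Inverse of [to_spherical()]
#'
#' @param longitude,latitude angles in radians.
#' @param frame an [eye_frame()] (or eye name).
#' @return n x 3 matrix of unit direction vectors from the eye centre.
#' @export
from_spherical <- function(longitude, latitude, frame = "right") {
  if (is.character(frame)) frame <- eye_frame(frame)
  cl <- cos(latitude)
  outer(cl * cos(longitude), frame$temporal) +
    outer(cl * sin(longitude), frame$anterior) +
    outer(sin(latitude), frame$up)
}

#' Extract the per-triangle field samples of an eyeball surface
#'
#' Replaces each eyeball surface triangle by one point (its centroid) with
#' one field value: the field magnitude of the eyeball tetrahedron owning
#' the triangle. The points are unwrapped to longitude/latitude about the
#' eye centre.
#'
#' @param phantom a `tissue_phantom` with eyes.
#' @param solution a `field_solution` on the same phantom.
#' @param eye `"right"` or `"left"`.
#' @return tibble with `eye`, `longitude`, `latitude`, `magnitude` (V/m)
#'   and the owning `element` id; one row per eyeball surface triangle.
#' @export
extract_eye_surface <- function(phantom, solution, eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (is.null(phantom$eye_centers))
    abort(paste0("phantom has no eyes; cannot extract the ", eye, " eye surface"))
  if (!is.null(solution$mesh_hash) && !identical(solution$mesh_hash, phantom$mesh_hash))
    abort("solution was computed on a different phantom")
  surf <- phantom$surface
  sel <- surf$label == "eyeball" & !is.na(surf$eye) & surf$eye == eye
  if (!any(sel)) abort(paste0("phantom has no ", eye, " eyeball surface"))
  tri <- surf[sel, , drop = FALSE]
  cc <- (phantom$nodes[tri$n1, , drop = FALSE] + phantom$nodes[tri$n2, , drop = FALSE] +
           phantom$nodes[tri$n3, , drop = FALSE]) / 3
  ll <- to_spherical(cc, phantom$eye_centers[[eye]], eye)
  tibble(
    eye = eye,
    longitude = ll$longitude,
    latitude = ll$latitude,
    magnitude = solution$magnitude[tri$tet],
    element = tri$tet
  )
}

#' Partition of the lower anterior ocular surface into named regions
#'
#' Three equal longitude bands of width pi/3 (1.047 rad) cover the anterior
#' half of the eye below the horizontal meridian: temporal `[0, pi/3]`,
#' central `[pi/3, 2 pi/3]` and nasal `[2 pi/3, pi]`, each with latitude
#' <= 0. The zone above each band (latitude > 0) is its "upper" zone; the
#' lower bands sharing a longitude boundary are its "adjacent" regions.
#'
#' @param eye `"right"` or `"left"`.
#' @return tibble of region specs: `eye`, `region`, `lon_min`, `lon_max`
#'   (radians), `hemisphere` (`"lower"`), and comma-separated `adjacent`
#'   region names.
#' @export
partition_regions <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  tibble(
    eye = eye,
    region = c("temporal", "central", "nasal"),
    lon_min = c(0, pi / 3, 2 * pi / 3),
    lon_max = c(pi / 3, 2 * pi / 3, pi),
    hemisphere = "lower",
    adjacent = c("central", "temporal,nasal", "central")
  )
}

#' Classify unwrapped points into evaluation zones
#'
#' Every point of the unwrapped eye surface belongs to exactly one zone:
#' one of the three lower anterior regions, the `upper` anterior zone, or
#' the `posterior` remainder.
#'
#' @param longitude,latitude angles in radians.
#' @param eye eye name (determines nothing here beyond bookkeeping; the
#'   partition is symmetric by construction).
#' @return character vector of zone names.
#' @export
classify_zone <- function(longitude, latitude, eye = "right") {
  zone <- rep("posterior", length(longitude))
  ant <- longitude >= 0 & longitude <= pi
  zone[ant & latitude > 0] <- "upper"
  regs <- partition_regions(eye)
  for (i in seq_len(nrow(regs))) {
    # half-open bands, closed at the nasal end, so the partition is exact
    in_band <- longitude >= regs$lon_min[i] &
      (if (i < nrow(regs)) longitude < regs$lon_max[i] else longitude <= regs$lon_max[i])
    zone[ant & latitude <= 0 & in_band] <- regs$region[i]
  }
  zone
}

#' Interpolate scattered surface samples onto a longitude/latitude grid
#'
#' Piecewise-linear interpolation on a Delaunay triangulation of the
#' (longitude, latitude) scatter, evaluated on a regular grid. Grid cells
#' outside the convex hull of the samples are masked (`NA`), never
#' extrapolated. The interpolation reproduces the sample values exactly at
#' the sample locations.
#'
#' @param samples tibble from [extract_eye_surface()] (columns `longitude`,
#'   `latitude`, `magnitude`).
#' @param resolution_deg grid cell size in degrees (default 1).
#' @return an `ocular_grid`: list with `longitude`, `latitude` (cell-centre
#'   vectors, radians), `magnitude` (matrix, V/m; rows follow longitude),
#'   `samples` and the interpolation method tag.
#' @export
interpolate_grid <- function(samples, resolution_deg = 1) {
  if (nrow(samples) < 3)
    abort("degenerate sample set: at least 3 samples are required for interpolation")
  if (any(!is.finite(samples$magnitude)) || any(samples$magnitude < 0))
    abort("sample field magnitudes must be finite and non-negative")
  dx <- diff(range(samples$longitude)); dy <- diff(range(samples$latitude))
  if (dx < 1e-9 || dy < 1e-9)
    abort("degenerate sample set: samples are collinear in longitude/latitude")
  step <- resolution_deg * pi / 180
  lon <- seq(min(samples$longitude), max(samples$longitude), by = step)
  lat <- seq(min(samples$latitude), max(samples$latitude), by = step)
  fit <- interp::interp(
    x = samples$longitude, y = samples$latitude, z = samples$magnitude,
    xo = lon, yo = lat, method = "linear", duplicate = "mean",
    extrap = FALSE
  )
  structure(list(
    longitude = fit$x, latitude = fit$y, magnitude = fit$z,
    samples = samples, method = "piecewise-linear (Delaunay)",
    eye = samples$eye[1] %||% NA_character_
  ), class = "ocular_grid")
}

#' Evaluate the interpolant of an [interpolate_grid()] fit at points
#'
#' @param grid an `ocular_grid`.
#' @param longitude,latitude query coordinates (radians).
#' @return interpolated field magnitudes (NA outside the sample hull).
#' @export
grid_lookup <- function(grid, longitude, latitude) {
  s <- grid$samples
  as.numeric(interp::interpp(
    x = s$longitude, y = s$latitude, z = s$magnitude,
    xo = longitude, yo = latitude, linear = TRUE, duplicate = "mean"
  )$z)
}

#' @export
print.ocular_grid <- function(x, ...) {
  cat(sprintf("<ocular_grid> %s eye: %d x %d cells, %d samples, %s\n",
              x$eye, length(x$longitude), length(x$latitude), nrow(x$samples),
              x$method))
  invisible(x)
}

# Maximum over a logical cell mask with deterministic tie-breaking:
# smallest longitude first, then smallest latitude.
grid_max <- function(grid, mask) {
  z <- grid$magnitude
  cand <- which(mask & !is.na(z), arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  vals <- z[cand]
  best <- max(vals)
  at <- cand[vals >= best - 1e-300, , drop = FALSE]
  ord <- order(grid$longitude[at[, 1]], grid$latitude[at[, 2]])
  at <- at[ord[1], ]
  list(value = best, longitude = grid$longitude[at[1]], latitude = grid$latitude[at[2]])
}

#' Locality report for one target region
#'
#' The locality criterion: the maximum interpolated field magnitude inside
#' the target region is compared with the maxima in the region's "upper"
#' zone (same longitude band, latitude > 0) and in its adjacent lower
#' region(s). Large positive differences mean the stimulation is local to
#' the target region.
#'
#' @param grid an `ocular_grid` covering the region.
#' @param region one row of [partition_regions()] (or a region name plus
#'   `eye`).
#' @param eye used when `region` is given as a name.
#' @param exclude_adjacent adjacent region names to leave out of the
#'   comparison (used by the montage pipeline to ignore fellow target
#'   regions: a montage that stimulates two neighbouring regions on purpose
#'   is scored against the remaining, unintended neighbours). If no
#'   adjacent region remains, `delta_adjacent` is `NA`.
#' @return tibble with one row: the in-region maximum, the upper and
#'   adjacent maxima with their grid coordinates, the global maximum outside
#'   the region, and the differences `delta_upper` and `delta_adjacent`
#'   (in-region max minus the respective outside max; negative when the
#'   outside field dominates).
#' @export
locality_report <- function(grid, region, eye = NULL,
                            exclude_adjacent = character(0)) {
  if (is.character(region)) {
    regs <- partition_regions(eye %||% grid$eye)
    region <- regs[regs$region == region, ]
    if (nrow(region) != 1) abort("unknown region name")
  }
  lon <- grid$longitude; lat <- grid$latitude
  lon_in <- lon >= region$lon_min & lon <= region$lon_max
  in_mask <- outer(lon_in, lat <= 0)
  up_mask <- outer(lon_in, lat > 0)
  if (!any(in_mask & !is.na(grid$magnitude)))
    abort("region lies entirely outside the interpolated grid mask")

  regs <- partition_regions(region$eye)
  adj_names <- setdiff(strsplit(region$adjacent, ",")[[1]], exclude_adjacent)
  adj_mask <- matrix(FALSE, length(lon), length(lat))
  for (a in adj_names) {
    ar <- regs[regs$region == a, ]
    adj_mask <- adj_mask | outer(lon >= ar$lon_min & lon <= ar$lon_max, lat <= 0)
  }

  m_in <- grid_max(grid, in_mask)
  m_up <- grid_max(grid, up_mask)
  m_adj <- grid_max(grid, adj_mask)
  m_out <- grid_max(grid, !in_mask)

  region_eye <- region$eye
  region_name <- region$region
  region_adjacent <- paste(adj_names, collapse = ",")
  tibble(
    eye = region_eye, region = region_name,
    max_in = m_in$value, lon_in = m_in$longitude, lat_in = m_in$latitude,
    max_upper = m_up$value %||% NA_real_,
    lon_upper = m_up$longitude %||% NA_real_,
    lat_upper = m_up$latitude %||% NA_real_,
    max_adjacent = m_adj$value %||% NA_real_,
    lon_adjacent = m_adj$longitude %||% NA_real_,
    lat_adjacent = m_adj$latitude %||% NA_real_,
    adjacent_regions = region_adjacent,
    max_outside = m_out$value %||% NA_real_,
    delta_upper = locality_delta(m_in$value, m_up$value %||% NA_real_),
    delta_adjacent = locality_delta(m_in$value, m_adj$value %||% NA_real_)
  )
}

#' Locality difference between two field maxima
#'
#' The decision quantity of the montage evaluation: the maximum field
#' magnitude in the region intended to be stimulated minus the maximum in a
#' competing zone. For example, temporal/nasal maxima of 2.16 and 0.68 V/m
#' give a difference of 1.48 V/m.
#'
#' @param max_in maximum field magnitude in the target region (V/m).
#' @param max_out maximum field magnitude in the competing zone (V/m).
#' @return `max_in - max_out` (V/m); negative when the outside dominates.
#' @export
#' @examples
#' locality_delta(2.16, 0.68) # 1.48
locality_delta <- function(max_in, max_out) {
  if (is.na(max_in) || is.na(max_out)) return(NA_real_)
  if (!is.finite(max_in) || !is.finite(max_out))
    abort("field maxima must be finite")
  if (max_in < 0 || max_out < 0)
    abort("field magnitudes are non-negative; got a negative input")
  max_in - max_out
}
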