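#' Tidy a phase comparison into its region reports
#'
#' @param x a `phase_comparison`.
#' @param ... unused.
#' @return tibble with one row per phase and target region.
#' @export
tidy.phase_comparison <- function(x, ...) {
  out <- x$reports
  out$montage <- x$montage
  dplyr::select(out, "montage", "phase", "pair", dplyr::everything())
}

#' One-row summary of a phase comparison
#'
#' @param x a `phase_comparison`.
#' @param ... unused.
#' @return tibble with the montage, currents, the minimum `delta_adjacent`
#'   of each phase and the recommended phase.
#' @export
glance.phase_comparison <- function(x, ...) {
  out <- tibble(
    montage = x$montage,
    currents = paste(x$currents, collapse = " & "),
    recommended_phase = x$recommended_phase
  )
  for (ph in x$phases)
    out[[paste0("min_delta_adjacent_", ph)]] <- unname(x$min_delta_adjacent[ph])
  out
}

#' Tidy a field solution into a per-element tibble
#'
#' @param x a `field_solution`.
#' @param ... unused.
#' @return tibble with element id, field components (V/m) and magnitude.
#' @export
tidy.field_solution <- function(x, ...) {
  tibble(
    element = seq_len(nrow(x$E)),
    Ex = x$E[, 1], Ey = x$E[, 2], Ez = x$E[, 3],
    magnitude = x$magnitude
  )
}

#' One-row summary of a field solution
#'
#' @param x a `field_solution`.
#' @param ... unused.
#' @return tibble with node/element counts, field range and solver
#'   residual.
#' @export
glance.field_solution <- function(x, ...) {
  tibble(
    n_nodes = length(x$V), n_elements = nrow(x$E),
    max_magnitude = max(x$magnitude), min_magnitude = min(x$magnitude),
    residual = x$residual
  )
}

#' Tidy an ocular grid into long format
#'
#' @param x an `ocular_grid`.
#' @param ... unused.
#' @return tibble with one row per unmasked grid cell: `longitude`,
#'   `latitude` (radians) and `magnitude` (V/m).
#' @export
tidy.ocular_grid <- function(x, ...) {
  out <- tibble(
    longitude = rep(x$longitude, times = length(x$latitude)),
    latitude = rep(x$latitude, each = length(x$longitude)),
    magnitude = as.vector(x$magnitude)
  )
  dplyr::filter(out, !is.na(.data$magnitude))
}
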