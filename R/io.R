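run_config_defaults <- function() {
  list(
    schema_version = 1L,
    phantom = phantom_config(),
    montage = "A+C",
    currents = NULL,
    conductivity = list(),
    phases = c("same", "anti"),
    grid_resolution_deg = 1,
    edge_length = 42,
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' YAML configuration for a full pipeline run. Any subset of the schema may
#' be given; the remaining fields take their documented defaults, and every
#' default is made explicit in the returned object (and therefore in the
#' provenance block of any report written from it). Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_run_config(raw)
}

#' Validate a run-configuration list against the schema
#'
#' @param raw named list following the run-config schema (may be empty; all
#'   defaults are filled in).
#' @return a validated `run_config`.
#' @export
validate_run_config <- function(raw) {
  def <- run_config_defaults()
  bad <- setdiff(names(raw), names(def))
  if (length(bad))
    abort(paste0("config schema violation: unknown key(s): ",
                 paste(bad, collapse = ", ")))
  if (!is.null(raw$phantom)) {
    badp <- setdiff(names(raw$phantom), names(def$phantom))
    if (length(badp))
      abort(paste0("config schema violation: unknown phantom key(s): ",
                   paste(badp, collapse = ", ")))
    def$phantom <- modifyList(def$phantom, raw$phantom)
  }
  def$phantom$eye_center <- as.numeric(def$phantom$eye_center)
  validate_phantom_config(def$phantom)
  if (!is.null(raw$conductivity)) {
    sig <- do.call(conductivity_map, raw$conductivity) # validates names and positivity
    def$conductivity <- raw$conductivity
    attr(def$conductivity, "resolved") <- sig
  }
  for (k in c("montage", "currents", "phases", "grid_resolution_deg",
              "edge_length", "output_dir", "schema_version")) {
    if (!is.null(raw[[k]])) def[[k]] <- raw[[k]]
  }
  if (!all(def$phases %in% c("same", "anti")))
    abort("config schema violation: `phases` must be a subset of same/anti")
  if (def$grid_resolution_deg <= 0)
    abort("config schema violation: `grid_resolution_deg` must be positive")
  if (!is.null(def$currents) && any(def$currents <= 0))
    abort("config schema violation: `currents` must be positive")
  structure(def, class = "run_config")
}

#' Save a run configuration
#'
#' @param config a `run_config` (or plain list following the schema).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$conductivity <- if (length(cfg$conductivity)) {
    c <- cfg$conductivity; attr(c, "resolved") <- NULL; c
  } else NULL
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Execute a full configured run
#'
#' Builds the phantom, runs the montage under the configured phases and
#' writes the report files.
#'
#' @param config a `run_config` from [load_config()].
#' @param write set `FALSE` to skip writing files.
#' @return the `phase_comparison`.
#' @export
run_from_config <- function(config, write = TRUE) {
  sigma <- attr(config$conductivity, "resolved") %||% conductivity_map()
  phantom <- build_head_phantom(config$phantom)
  montage <- montage_catalog(config$montage, currents = config$currents)
  comparison <- run_arrangement(phantom, montage, sigma = sigma,
                                phases = config$phases,
                                grid_resolution_deg = config$grid_resolution_deg,
                                edge_length = config$edge_length)
  if (write) write_report(comparison, config$output_dir, config = config)
  comparison
}

#' Write a phase comparison to JSON and CSV
#'
#' The JSON file carries the full comparison plus a provenance block
#' (schema version, configuration, seed, conductivities, solver residuals,
#' grid resolution and a configuration hash) sufficient to re-run the
#' producing command; the CSV holds the tabular region reports, one row
#' per phase and region.
#'
#' @param comparison a `phase_comparison`.
#' @param dir output directory (created if absent).
#' @param config optional `run_config` to embed in the provenance.
#' @param stem file name stem (default from the montage name).
#' @return named character vector of the files written.
#' @export
write_report <- function(comparison, dir, config = NULL, stem = NULL) {
  if (!inherits(comparison, "phase_comparison"))
    abort("`comparison` must be a phase_comparison")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) abort(paste0("cannot create output directory: ", dir))
  }
  stem <- stem %||% paste0("report_", gsub("[^A-Za-z0-9]+", "_", comparison$montage))
  json_path <- file.path(dir, paste0(stem, ".json"))
  csv_path <- file.path(dir, paste0(stem, ".csv"))

  cfg <- if (!is.null(config)) unclass(config) else NULL
  if (!is.null(cfg)) attr(cfg$conductivity, "resolved") <- NULL
  payload <- list(
    montage = comparison$montage,
    currents = comparison$currents,
    phases = comparison$phases,
    recommended_phase = comparison$recommended_phase,
    min_delta_adjacent = as.list(comparison$min_delta_adjacent),
    reports = comparison$reports,
    provenance = list(
      schema_version = 1L,
      config = cfg,
      phantom_config = comparison$provenance$phantom_config,
      mesh_hash = comparison$provenance$mesh_hash,
      config_hash = rlang::hash(list(cfg, comparison$provenance$phantom_config)),
      grid_resolution_deg = comparison$provenance$grid_resolution_deg,
      solver_residuals = comparison$provenance$solver_residuals,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  write.csv(comparison$reports, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a written report back
#'
#' @param path JSON report path.
#' @return list mirroring the structure written by [write_report()], with
#'   `reports` as a tibble.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$reports <- as_tibble(x$reports)
  x
}

#' Export a field solution as a legacy VTK unstructured grid
#'
#' ASCII VTK with the tetrahedral mesh, tissue labels, the field magnitude
#' as a cell scalar and the field vector as cell vectors; readable by
#' ParaView and meshio.
#'
#' @param phantom a `tissue_phantom`.
#' @param solution optional `field_solution` on the same phantom.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(phantom, solution = NULL, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nrow(phantom$nodes); m <- nrow(phantom$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "tissue phantom field export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(phantom$nodes, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, m * 5L), con)
  utils::write.table(cbind(4L, phantom$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(phantom$labels))), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS field_magnitude double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(solution$magnitude, digits = 9, trim = TRUE), con)
    writeLines("VECTORS field double", con)
    utils::write.table(format(solution$E, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export per-element field magnitudes as CSV
#'
#' @param solution a `field_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(solution, path) {
  write.csv(data.frame(element = seq_along(solution$magnitude),
                       magnitude = solution$magnitude),
            path, row.names = FALSE)
  invisible(path)
}
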