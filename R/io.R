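#' Write a grid to a directory of plain-text files
#'
#' Self-describing ASCII serialization: one CSV matrix per field
#' (`bed_depth`, `landtype` as integer codes, `manning`, `active`) plus a
#' JSON metadata file with the geometry, the land-type code map and the
#' open-boundary table. Matrices are written with rows indexing x (east) and
#' columns indexing y (north).
#'
#' @param grid A [make_grid()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wm(grid$bed_depth, "bed_depth.csv")
  wm(matrix(match(grid$landtype, LAND_TYPES), grid$nx, grid$ny), "landtype.csv")
  wm(grid$manning, "manning.csv")
  wm(grid$active * 1L, "active.csv")
  meta <- list(nx = grid$nx, ny = grid$ny, dx = grid$dx, dy = grid$dy,
               landtype_codes = as.list(stats::setNames(seq_along(LAND_TYPES), LAND_TYPES)),
               open_boundary = grid$open_boundary)
  jsonlite::write_json(meta, file.path(dir, "grid.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a grid written by [write_grid()]
#' @param dir Directory containing the serialized grid.
#' @return A [make_grid()] object.
#' @export
read_grid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  rm_ <- function(f) unname(as.matrix(utils::read.table(file.path(dir, f), sep = ",")))
  codes <- unlist(meta$landtype_codes)
  lt_int <- rm_("landtype.csv")
  lt <- matrix(names(codes)[match(lt_int, codes)], meta$nx, meta$ny)
  ob <- as.data.frame(meta$open_boundary)
  if (nrow(ob) == 0) ob <- NULL
  g <- make_grid(meta$nx, meta$ny, meta$dx, meta$dy,
                 bed_depth = rm_("bed_depth.csv"), landtype = lt,
                 active = rm_("active.csv") == 1, open_boundary = ob)
  g$manning <- rm_("manning.csv") # preserve possibly overridden roughness
  g
}

#' Write a source table
#'
#' CSV with columns `name, i, j, rate_mg_per_s, window_start, window_end,
#' routing, wetland_id` (window in hours of day).
#'
#' @param sources List of [discharge_source()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sources <- function(sources, path) {
  df <- do.call(rbind, lapply(sources, function(s) {
    data.frame(name = s$name, i = s$i, j = s$j, rate_mg_per_s = s$rate,
               window_start = s$window[1], window_end = s$window[2],
               routing = s$routing, wetland_id = s$wetland_id)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a source table written by [write_sources()]
#' @param path CSV path.
#' @return List of [discharge_source()] objects.
#' @export
read_sources <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(r) {
    discharge_source(df$name[r], df$i[r], df$j[r], df$rate_mg_per_s[r],
                     window = c(df$window_start[r], df$window_end[r]),
                     routing = df$routing[r], wetland_id = df$wetland_id[r])
  })
}

#' Load a keyed simulation configuration
#'
#' YAML file with optional sections `catchment` (arguments of
#' [make_toy_catchment()]), `kinetics` ([kinetic_params()]), `soil`
#' ([soil_context()]), `hydro` ([hydro_params()]), `transport`
#' ([transport_params()]) and `run` (duration_days, dt, transport_stride,
#' save_interval, station_interval). Missing sections fall back to package
#' defaults.
#'
#' @param path YAML file path.
#' @return Named list of resolved configuration objects.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  resolve <- function(fn, args) do.call(fn, as.list(args %||% list()))
  list(catchment = resolve(make_toy_catchment, cfg$catchment),
       kinetics = resolve(kinetic_params, cfg$kinetics),
       soil = resolve(soil_context, cfg$soil),
       hydro = resolve(hydro_params, cfg$hydro),
       transport = resolve(transport_params, cfg$transport),
       run = cfg$run %||% list())
}

#' Run a scenario from a configuration
#'
#' Convenience wrapper chaining [load_config()], [build_scenario()] and
#' [run_simulation()]; used by the command-line interface.
#'
#' @param config Path to a YAML configuration or a pre-loaded list.
#' @param scenario Scenario name (`"SC1"`, `"SC2"`, `"SC3"`, `"NonEco"`).
#' @param ... Overrides passed on to [run_simulation()].
#' @return A [run_simulation()] result.
#' @export
simulate_from_config <- function(config, scenario = "SC1", ...) {
  cfg <- if (is.character(config)) load_config(config) else config
  sc <- build_scenario(scenario, cfg$catchment, k = cfg$kinetics)
  run_args <- cfg$run
  if (!is.null(run_args$duration_days)) {
    run_args$duration <- run_args$duration_days * 86400
    run_args$duration_days <- NULL
  }
  args <- utils::modifyList(
    c(list(scenario = sc, hparams = cfg$hydro, tparams = cfg$transport,
           k = cfg$kinetics, context = cfg$soil), run_args),
    list(...))
  do.call(run_simulation, args)
}

#' Write run outputs to a directory
#'
#' Plain-text outputs: `stations.csv` (long station series), `budget.csv`,
#' `manifest.json` (the fully resolved configuration), the final fields as
#' CSV matrices under `final/`, and optionally every saved snapshot under
#' `snapshots/<time>/`.
#'
#' @param run A [run_simulation()] result.
#' @param dir Output directory.
#' @param snapshots Also write every saved field snapshot (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_run_output <- function(run, dir, snapshots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$stations_long, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  b <- run$budget
  utils::write.csv(data.frame(field = names(unclass(b)),
                              kg = unlist(unclass(b))),
                   file.path(dir, "budget.csv"), row.names = FALSE)
  cfg <- run$config
  cfg$hparams <- unclass(cfg$hparams); cfg$tparams <- unclass(cfg$tparams)
  cfg$k <- unclass(cfg$k); cfg$context <- unclass(cfg$context)
  manifest <- list(scenario = run$name, config = cfg,
                   snapshot_times = run$snapshot_times)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  fdir <- file.path(dir, "final")
  dir.create(fdir, showWarnings = FALSE)
  wm <- function(x, f) utils::write.table(
    x, file.path(fdir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  for (f in c("zeta", "c", "Sl", "Ss", "Pl")) wm(run$final[[f]], paste0(f, ".csv"))
  if (snapshots) {
    for (ii in seq_along(run$snapshot_times)) {
      sdir <- file.path(dir, "snapshots", sprintf("t%09.0f", run$snapshot_times[ii]))
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      for (f in names(run$snapshots)) {
        utils::write.table(run$snapshots[[f]][[ii]], file.path(sdir, paste0(f, ".csv")),
                           sep = ",", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(dir)
}
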