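#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional `sonar`, `navigation`, `mapping` and
#' `classification` blocks plus a `seed`; any key not given keeps its
#' default (the reference constants baked into [sonar_config()] and
#' [run_config()]). Unknown keys and out-of-range values are rejected.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed YAML in ", path, ": ", conditionMessage(e)))
  if (is.null(y)) y <- list()
  known_blocks <- c("sonar", "navigation", "mapping", "classification",
                    "seed")
  unknown <- setdiff(names(y), known_blocks)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  sonar_args <- y$sonar %||% list()
  bad <- setdiff(names(sonar_args), names(formals(sonar_config)))
  if (length(bad)) stop("unknown sonar keys: ", paste(bad, collapse = ", "))
  sonar <- do.call(sonar_config, sonar_args)
  nav <- y$navigation %||% list()
  mapb <- y$mapping %||% list()
  clsb <- y$classification %||% list()
  nav_map <- c(step_m = "step_m", obstacle_trigger_m = "obstacle_trigger_m",
               frontal_sector_deg = "frontal_sector_deg",
               sidestep_m = "sidestep_m")
  map_map <- c(grid_n = "grid_n", resolution_m = "resolution_m",
               inflate_cells = "inflate_cells",
               closing_iterations = "closing_iterations",
               map_every_steps = "map_every_steps")
  cls_map <- c(max_range_m = "classify_max_range_m")
  args <- list(sonar = sonar)
  take <- function(block, mapping, blockname) {
    bad <- setdiff(names(block), names(mapping))
    if (length(bad)) stop("unknown ", blockname, " keys: ",
                          paste(bad, collapse = ", "))
    for (k in names(block)) args[[mapping[[k]]]] <<- block[[k]]
  }
  take(nav, nav_map, "navigation")
  take(mapb, map_map, "mapping")
  take(clsb, cls_map, "classification")
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Serialize a run_config to a plain named list (for snapshots).
config_as_list <- function(config) {
  list(sonar = unclass(config$sonar),
       navigation = config[c("step_m", "obstacle_trigger_m",
                             "frontal_sector_deg", "sidestep_m")],
       mapping = config[c("grid_n", "resolution_m", "inflate_cells",
                          "closing_iterations", "map_every_steps")],
       classification = list(max_range_m = config$classify_max_range_m),
       seed = config$seed)
}

#' Write the artifacts of a mission run
#'
#' A run directory is self-describing: the configuration snapshot plus the
#' seed reproduce it exactly. Writes `trajectory.csv` (x, y, heading,
#' step, mode), `map.png` + `map.json` (georeferenced binary map),
#' `detections.jsonl` (one JSON detection record per line, with world
#' coordinates, pose and the C/T/P annotation), `report.json` (status,
#' counts, config hash) and `config.yaml`.
#'
#' @param rundir Output directory (created if missing).
#' @param result A `mission_result` from [run_mission()].
#' @param config The [run_config()] used.
#' @return Invisibly, the run directory path.
#' @export
write_run_artifacts <- function(rundir, result, config) {
  dir.create(rundir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$trajectory, file.path(rundir, "trajectory.csv"),
                   row.names = FALSE)
  write_map(result$map, file.path(rundir, "map.png"),
            file.path(rundir, "map.json"))
  det_path <- file.path(rundir, "detections.jsonl")
  con <- file(det_path, "w")
  if (nrow(result$detections)) {
    for (i in seq_len(nrow(result$detections))) {
      row <- result$detections[i, ]
      writeLines(jsonlite::toJSON(list(
        range_m = row$range_m, azimuth_deg = row$azimuth_deg,
        C = row$C, T = row$T, P = row$P,
        world_x = row$world_x, world_y = row$world_y,
        pose = c(row$pose_x, row$pose_y, row$pose_h)),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  close(con)
  cfg_path <- file.path(rundir, "config.yaml")
  yaml::write_yaml(config_as_list(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(list(
    status = result$status, collided = result$collided,
    n_steps = max(result$trajectory$step),
    n_detections = nrow(result$detections),
    occupied_cells = sum(result$map$grid),
    config_hash = cfg_hash, seed = config$seed),
    file.path(rundir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(rundir)
}
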