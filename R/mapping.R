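#' Create an empty occupancy map
#'
#' A world-fixed binary grid of `grid_n` x `grid_n` cells of
#' `resolution_m` x `resolution_m` each (default 2000 x 2000 at 5 cm: a
#' 100 m x 100 m window). The map is anchored so that `start_pose` falls at
#' the center cell. Cells are 0-based-free / occupied booleans; cells the
#' robot has traversed are remembered and always forced free — an observed
#' open path beats any inflated object.
#'
#' @param start_pose Robot start pose `c(x, y, heading_deg)` (only x, y
#'   used for anchoring).
#' @param config A [run_config()].
#' @return A list of class `"occupancy_map"`: `grid` (logical matrix,
#'   rows = y cells, cols = x cells), `trajectory_cells` (logical matrix),
#'   `resolution`, `origin` (world coordinates of the lower-left corner of
#'   cell (1,1)), `trajectory` (n x 2 matrix of traversed waypoints).
#' @export
occupancy_map <- function(start_pose = c(0, 0, 0), config = run_config()) {
  n <- config$grid_n
  res <- config$resolution_m
  origin <- c(start_pose[1] - (n / 2 - 0.5) * res - res / 2,
              start_pose[2] - (n / 2 - 0.5) * res - res / 2)
  structure(list(grid = matrix(FALSE, n, n),
                 trajectory_cells = matrix(FALSE, n, n),
                 resolution = res, origin = origin,
                 trajectory = matrix(start_pose[1:2], 1, 2)),
            class = "occupancy_map")
}

# world (x, y) -> cell (row = y index, col = x index); NA outside the grid.
world_to_cell <- function(map, x, y) {
  col <- floor((x - map$origin[1]) / map$resolution) + 1
  row <- floor((y - map$origin[2]) / map$resolution) + 1
  n <- nrow(map$grid)
  bad <- col < 1 | col > n | row < 1 | row > n
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

# cell center -> world coordinates.
cell_to_world <- function(map, row, col) {
  cbind(x = map$origin[1] + (col - 0.5) * map$resolution,
        y = map$origin[2] + (row - 0.5) * map$resolution)
}

# Transform robot-frame detection offsets to world coordinates.
robot_to_world <- function(pose, x_r, y_r) {
  h <- pose[3] * pi / 180
  cbind(x = pose[1] + cos(h) * x_r - sin(h) * y_r,
        y = pose[2] + sin(h) * x_r + cos(h) * y_r)
}

#' Insert detected objects and inflate them
#'
#' Places each detection into its world cell and inflates it to a square of
#' `inflate_cells` x `inflate_cells` cells around that cell (default 20 x 20
#' cells, i.e. a 1 m^2 obstacle patch: a detected point is treated as part
#' of an object of roughly that size, delineating safe clearance).
#' Trajectory cells are forced free afterward. Detections falling outside
#' the grid are dropped with a warning.
#'
#' @param map An [occupancy_map()].
#' @param objects Detection data.frame from [process_acquisition()]
#'   (robot-frame `x`, `y` columns).
#' @param robot_pose Pose `c(x, y, heading_deg)` at acquisition.
#' @param config A [run_config()].
#' @return The updated map.
#' @export
insert_and_inflate <- function(map, objects, robot_pose,
                               config = run_config()) {
  if (!nrow(objects)) return(map)
  w <- robot_to_world(robot_pose, objects$x, objects$y)
  cells <- world_to_cell(map, w[, 1], w[, 2])
  n <- nrow(map$grid)
  half_lo <- floor((config$inflate_cells - 1) / 2)      # 9 for 20 cells
  half_hi <- config$inflate_cells - 1 - half_lo         # 10 for 20 cells
  for (k in seq_len(nrow(cells))) {
    if (is.na(cells[k, 1])) {
      warning("detection outside map grid dropped")
      next
    }
    rows <- max(1, cells[k, 1] - half_lo):min(n, cells[k, 1] + half_hi)
    cols <- max(1, cells[k, 2] - half_lo):min(n, cells[k, 2] + half_hi)
    map$grid[rows, cols] <- TRUE
  }
  map$grid[map$trajectory_cells] <- FALSE
  map
}

#' Connect nearby inflated squares
#'
#' Joins neighboring occupied squares into continuous object regions by
#' iterated binary morphological closing with a 3 x 3 box element
#' (`iterations` passes, default 3). This is the interpolation step that
#' turns isolated detection squares into continuous object borders.
#' Trajectory cells stay free.
#'
#' @param map An [occupancy_map()].
#' @param iterations Number of closing passes.
#' @return The updated map.
#' @export
connect_inflated <- function(map, iterations = 3) {
  if (iterations == 0) return(map)
  g <- map$grid * 1L
  kern <- matrix(1L, 3, 3)
  for (i in seq_len(iterations)) g <- EBImage::closing(g, kern)
  map$grid <- g > 0
  map$grid[map$trajectory_cells] <- FALSE
  map
}

#' Mark a traversed segment on the map
#'
#' Records the robot's path from `from` to `to` (world meters): cells along
#' the segment become trajectory cells, are cleared, and stay free forever.
#'
#' @param map An [occupancy_map()].
#' @param from,to World points `c(x, y)`.
#' @return The updated map.
#' @export
mark_trajectory <- function(map, from, to) {
  L <- sqrt(sum((to - from)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(L / (map$resolution / 2)) + 1))
  px <- from[1] + ts * (to[1] - from[1])
  py <- from[2] + ts * (to[2] - from[2])
  cells <- world_to_cell(map, px, py)
  ok <- !is.na(cells[, 1])
  idx <- cbind(cells[ok, 1], cells[ok, 2])
  map$trajectory_cells[idx] <- TRUE
  map$grid[idx] <- FALSE
  map$trajectory <- rbind(map$trajectory, to)
  map
}

#' Periodic map integration
#'
#' Newly localized objects are buffered and integrated only every
#' `map_every_steps` cruise steps (default 5 steps = 2.5 m):
#' [insert_and_inflate()] followed by [connect_inflated()]. Off-cadence
#' calls leave the occupied set untouched and return the grown buffer.
#'
#' @param map An [occupancy_map()].
#' @param step_counter Number of cruise steps taken so far.
#' @param pending_objects Buffered detections (data.frame rows carrying
#'   robot-frame `x`, `y` and the pose they were seen from as `pose_x`,
#'   `pose_y`, `pose_h`).
#' @param config A [run_config()].
#' @return List `map`, `pending_objects` (emptied if integrated).
#' @export
update_cycle <- function(map, step_counter, pending_objects,
                         config = run_config()) {
  if (step_counter %% config$map_every_steps != 0 || !nrow(pending_objects))
    return(list(map = map, pending_objects = pending_objects))
  for (p in split(pending_objects,
                  interaction(pending_objects$pose_x, pending_objects$pose_y,
                              pending_objects$pose_h, drop = TRUE))) {
    map <- insert_and_inflate(map, p, c(p$pose_x[1], p$pose_y[1], p$pose_h[1]),
                              config)
  }
  map <- connect_inflated(map, config$closing_iterations)
  list(map = map,
       pending_objects = pending_objects[0, , drop = FALSE])
}

#' Extract the free-space-facing object contour on one side of the trail
#'
#' Boundary cells of occupied regions (occupied cells with a free 4-neighbor)
#' are assigned to the left or right of the traversed trajectory by the sign
#' of their lateral offset; along the trajectory's arc length, the boundary
#' cell nearest the trail in each bin forms the contour — the edge of the
#' obstacles as seen from the free path.
#'
#' @param map An [occupancy_map()] whose `trajectory` has >= 2 waypoints.
#' @param side `"left"` or `"right"` of the direction of travel.
#' @param bin_m Arc-length bin width in meters.
#' @return An n x 2 matrix of world points ordered along the trail; empty
#'   (0 x 2, with attribute `empty = TRUE`) if the side has no occupied
#'   cells.
#' @export
extract_contour <- function(map, side = c("left", "right"), bin_m = 0.1) {
  side <- match.arg(side)
  occ <- which(map$grid, arr.ind = TRUE)
  empty <- matrix(numeric(0), 0, 2)
  if (!nrow(occ)) { attr(empty, "empty") <- TRUE; return(empty) }
  g <- map$grid
  pad <- rbind(FALSE, cbind(FALSE, g, FALSE), FALSE)  # n+2 x n+2
  # vectorized 4-neighbor free test
  at <- function(dr, dc) pad[cbind(occ[, 1] + 1 + dr, occ[, 2] + 1 + dc)]
  boundary <- !(at(-1, 0) & at(1, 0) & at(0, -1) & at(0, 1))
  occ <- occ[boundary, , drop = FALSE]
  if (!nrow(occ)) { attr(empty, "empty") <- TRUE; return(empty) }
  pts <- cell_to_world(map, occ[, 1], occ[, 2])
  proj <- project_on_polyline(pts, map$trajectory)
  want <- if (side == "left") proj$lateral > 0 else proj$lateral < 0
  pts <- pts[want, , drop = FALSE]
  proj_s <- proj$s[want]; lat <- abs(proj$lateral[want])
  if (!nrow(pts)) { attr(empty, "empty") <- TRUE; return(empty) }
  bins <- floor(proj_s / bin_m)
  keep <- vapply(split(seq_along(bins), bins),
                 function(ii) ii[which.min(lat[ii])], 0L)
  keep <- keep[order(proj_s[keep])]
  pts[keep, , drop = FALSE]
}

# Project points onto a polyline: returns arc length `s` of the foot point
# and signed lateral offset (positive to the left of travel direction).
project_on_polyline <- function(pts, line) {
  nseg <- nrow(line) - 1
  if (nseg < 1) stop("trajectory needs >= 2 waypoints")
  cum <- c(0, cumsum(sqrt(rowSums((line[-1, , drop = FALSE] -
                                     line[-nrow(line), , drop = FALSE])^2))))
  best_d <- rep(Inf, nrow(pts))
  best_s <- numeric(nrow(pts)); best_lat <- numeric(nrow(pts))
  for (k in seq_len(nseg)) {
    a <- line[k, ]; b <- line[k + 1, ]
    v <- b - a; L2 <- sum(v^2)
    if (L2 < 1e-12) next
    t <- ((pts[, 1] - a[1]) * v[1] + (pts[, 2] - a[2]) * v[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    fx <- a[1] + t * v[1]; fy <- a[2] + t * v[2]
    d <- sqrt((pts[, 1] - fx)^2 + (pts[, 2] - fy)^2)
    cross <- v[1] * (pts[, 2] - a[2]) - v[2] * (pts[, 1] - a[1])
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_s[upd] <- cum[k] + t[upd] * sqrt(L2)
    best_lat[upd] <- sign(cross[upd]) * d[upd]
  }
  list(s = best_s, lateral = best_lat, dist = best_d)
}

#' Export an occupancy map as PNG plus JSON sidecar
#'
#' Writes the binary grid as a grayscale PNG (occupied = white) and a JSON
#' sidecar with the origin, resolution and grid size, so the image is fully
#' georeferenced.
#'
#' @param map An [occupancy_map()].
#' @param path_png,path_json Output paths.
#' @return Invisibly, the two paths.
#' @export
write_map <- function(map, path_png, path_json = sub("\\.png$", ".json",
                                                     path_png)) {
  img <- map$grid[nrow(map$grid):1, ] * 1  # row 1 at the bottom -> image top
  png::writePNG(img, path_png)
  jsonlite::write_json(list(origin = map$origin, resolution = map$resolution,
                            grid_n = nrow(map$grid),
                            occupied_cells = sum(map$grid)),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_png, path_json))
}
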