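#' Robot state for the reactive navigation loop
#'
#' @param pose Pose `c(x, y, heading_deg)`.
#' @return A list of class `"robot_state"` with fields `pose`, `step_count`
#'   (cruise steps taken), `mode` (`"cruise"`, `"avoid_right"` or
#'   `"avoid_forward_check"`), `pre_avoidance_heading`.
#' @export
robot_state <- function(pose = c(0, 0, 0)) {
  structure(list(pose = pose, step_count = 0L, mode = "cruise",
                 pre_avoidance_heading = pose[3]),
            class = "robot_state")
}

#' Is there an obstacle ahead?
#'
#' True iff any object detected in the most recent acquisition lies closer
#' than `obstacle_trigger_m` (1.2 m) within the frontal sector
#' (+/- `frontal_sector_deg`, default 30 degrees, around the current
#' heading). The instantaneous detections drive the avoidance trigger; the
#' integrated map is used for reporting and later path planning, not for
#' this reflex.
#'
#' @param objects Detections from [process_acquisition()] (robot frame).
#' @param config A [run_config()].
#' @param map Optionally an [occupancy_map()]; if given, occupied cells in
#'   the frontal sector also count. Off by default: inflated cells extend
#'   0.5 m beyond each detected point, so consulting the map for this
#'   reflex would see phantom blockage on any trail narrower than the
#'   inflation; the map serves reporting and later planning instead.
#' @param pose Robot pose, required when `map` is given.
#' @return Logical scalar.
#' @export
obstacle_ahead <- function(objects, config = run_config(), map = NULL,
                           pose = NULL) {
  hit <- nrow(objects) > 0 &&
    any(objects$range_m < config$obstacle_trigger_m &
          abs(objects$azimuth_deg) <= config$frontal_sector_deg)
  if (hit || is.null(map)) return(hit)
  stopifnot(!is.null(pose))
  occ <- which(map$grid, arr.ind = TRUE)
  if (!nrow(occ)) return(FALSE)
  w <- cell_to_world(map, occ[, 1], occ[, 2])
  dx <- w[, 1] - pose[1]; dy <- w[, 2] - pose[2]
  rng <- sqrt(dx^2 + dy^2)
  az <- ((atan2(dy, dx) * 180 / pi - pose[3] + 180) %% 360) - 180
  any(rng < config$obstacle_trigger_m &
        abs(az) <= config$frontal_sector_deg)
}

#' One step of the bug-algorithm automaton
#'
#' Reactive obstacle avoidance: cruise straight in 0.5 m steps; when the
#' way ahead is blocked, turn 90 degrees right; sidestep 1 m while the
#' original direction is blocked, turning back left after each sidestep to
#' re-check; once clear, resume the pre-avoidance heading. If the sidestep
#' direction itself is blocked, turn a further 90 degrees right
#' (wall-following fallback).
#'
#' @param state A [robot_state()].
#' @param ahead Result of [obstacle_ahead()] for the current acquisition.
#' @param config A [run_config()].
#' @return The updated state; `$moved` holds the translation length of this
#'   step (0, `step_m` or `sidestep_m`).
#' @export
bug_step <- function(state, ahead, config = run_config()) {
  advance <- function(st, d) {
    h <- st$pose[3] * pi / 180
    st$pose[1:2] <- st$pose[1:2] + d * c(cos(h), sin(h))
    st
  }
  state$moved <- 0
  if (state$mode == "cruise") {
    if (!ahead) {
      state <- advance(state, config$step_m)
      state$step_count <- state$step_count + 1L
      state$moved <- config$step_m
    } else {
      state$pre_avoidance_heading <- state$pose[3]
      state$pose[3] <- state$pose[3] - 90
      state$mode <- "avoid_right"
    }
  } else if (state$mode == "avoid_right") {
    if (!ahead) {
      state <- advance(state, config$sidestep_m)
      state$moved <- config$sidestep_m
      state$pose[3] <- state$pose[3] + 90   # turn back to original direction
      state$mode <- "avoid_forward_check"
    } else {
      state$pose[3] <- state$pose[3] - 90   # sidestep blocked: keep turning
    }
  } else if (state$mode == "avoid_forward_check") {
    if (!ahead) {
      state$pose[3] <- state$pre_avoidance_heading
      state$mode <- "cruise"
      state <- advance(state, config$step_m)
      state$step_count <- state$step_count + 1L
      state$moved <- config$step_m
    } else {
      state$pose[3] <- state$pose[3] - 90   # still blocked: back to sidestepping
      state$mode <- "avoid_right"
    }
  }
  state
}

#' Run a full autonomous mission
#'
#' The complete sense-plan-act loop: at each acquisition point, synthesize
#' echoes at the three headings (-60, 0, +60; or their sum in summed-beam
#' mode), run the perception chain, check for an obstacle ahead, take one
#' bug-algorithm step, and feed detections to the periodic map integration.
#' Terminates at `max_steps` loop iterations or when the robot leaves the
#' scene bounds. Entering an object footprint is a collision and raises an
#' error carrying the full state.
#'
#' @param scene A [sonar_scene()].
#' @param start_pose Pose `c(x, y, heading_deg)` in free space.
#' @param config A [run_config()].
#' @param max_steps Maximum number of loop iterations.
#' @param summed_beam If `TRUE`, process the superposition of the three
#'   heading recordings instead of the three separately.
#' @return A list of class `"mission_result"`: `trajectory` (data.frame
#'   `x, y, heading, step, mode`), `map` (the final [occupancy_map()]),
#'   `detections` (world-frame log with poses), `status`
#'   (`"completed"`, `"exited_bounds"`), `collided` (FALSE on success).
#' @export
run_mission <- function(scene, start_pose, config = run_config(),
                        max_steps = 40, summed_beam = FALSE) {
  validate_scene(scene)
  chirp <- generate_chirp(config$sonar)
  state <- robot_state(start_pose)
  map <- occupancy_map(start_pose, config)
  pending <- data.frame()
  traj <- data.frame(x = start_pose[1], y = start_pose[2],
                     heading = start_pose[3], step = 0L, mode = "cruise")
  det_log <- list()
  status <- "completed"
  seed0 <- derive_seed(config$seed, "mission_noise")
  for (it in seq_len(max_steps)) {
    recs <- lapply(c(-60, 0, 60), function(off)
      synthesize_echoes(scene, state$pose, off, config$sonar,
                        seed = seed0 + 3L * it + (off / 60 + 1L)))
    input <- if (summed_beam) sum_headings(recs) else recs
    dets <- process_acquisition(input, chirp, config$sonar)
    if (nrow(dets)) {
      dets$pose_x <- state$pose[1]; dets$pose_y <- state$pose[2]
      dets$pose_h <- state$pose[3]
      w <- robot_to_world(state$pose, dets$x, dets$y)
      dets$world_x <- w[, 1]; dets$world_y <- w[, 2]
      det_log[[length(det_log) + 1]] <- dets
      pending <- if (nrow(pending)) rbind(pending, dets) else dets
    }
    ahead <- obstacle_ahead(dets, config)
    prev <- state$pose[1:2]
    state <- bug_step(state, ahead, config)
    if (state$moved > 0) {
      if (segment_hits_object(scene, prev, state$pose[1:2]))
        stop(mission_failure(state, traj, "collision"))
      map <- mark_trajectory(map, prev, state$pose[1:2])
    }
    traj <- rbind(traj, data.frame(x = state$pose[1], y = state$pose[2],
                                   heading = state$pose[3],
                                   step = state$step_count,
                                   mode = state$mode))
    if (nrow(pending)) {
      up <- update_cycle(map, state$step_count, pending, config)
      map <- up$map; pending <- up$pending_objects
    }
    b <- scene$bounds
    if (state$pose[1] < b[1] || state$pose[1] > b[2] ||
        state$pose[2] < b[3] || state$pose[2] > b[4]) {
      status <- "exited_bounds"
      break
    }
  }
  # integrate whatever is still buffered so the final map is complete
  if (nrow(pending)) {
    up <- update_cycle(map, config$map_every_steps, pending, config)
    map <- up$map
  }
  detections <- if (length(det_log)) do.call(rbind, det_log) else
    data.frame()
  structure(list(trajectory = traj, map = map, detections = detections,
                 status = status, collided = FALSE),
            class = "mission_result")
}

robot_in_object <- function(scene, p) {
  for (obj in scene$objects)
    if (point_in_polygon(p[1], p[2], obj$footprint)) return(TRUE)
  FALSE
}

# Collision test for the whole swept segment, sampled every 5 cm.
segment_hits_object <- function(scene, from, to, step = 0.05) {
  L <- sqrt(sum((to - from)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
  for (t in ts)
    if (robot_in_object(scene, from + t * (to - from))) return(TRUE)
  FALSE
}

mission_failure <- function(state, traj, why) {
  structure(class = c("mission_failure", "error", "condition"),
            list(message = paste0("mission failure: ", why, " at pose (",
                                  paste(signif(state$pose, 4), collapse = ", "),
                                  ")"),
                 call = NULL, state = state, trajectory = traj))
}
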