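#' 2D scenes, objects and reflectors
#'
#' The world model is deliberately flat and acoustic: a scene is a bounded
#' 2D region containing objects, each object a closed polygonal footprint
#' carrying point reflectors. A reflector is either `specular` (a strong
#' glint, e.g. a smooth artificial surface) or `diffuse_member` (one of the
#' many weak scatterers that make up vegetation-like echo trains).
#'
#' Conventions: world frame x right / y up in meters; headings measured
#' counter-clockwise from +x in degrees; azimuths positive to the robot's
#' left (counter-clockwise).
#'
#' @param position Numeric length-2, meters, world frame.
#' @param strength Reflection gain in (0, 1].
#' @param kind `"specular"` or `"diffuse_member"`.
#' @return `reflector()`: a one-row data.frame with columns `x, y, strength,
#'   kind`.
#' @export
reflector <- function(position, strength, kind = c("specular", "diffuse_member")) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 2, all(is.finite(position)),
            is.finite(strength), strength > 0, strength <= 1)
  data.frame(x = position[1], y = position[2], strength = strength,
             kind = kind, stringsAsFactors = FALSE)
}

#' @rdname reflector
#' @param footprint Closed polygon as an n x 2 matrix (meters); first and
#'   last vertex need not repeat.
#' @param reflectors A data.frame of reflectors (rows as from [reflector()]).
#' @param label `"plant"` or `"non_plant"`.
#' @param id Object identifier string.
#' @return `scene_object()`: a list of class `"scene_object"`.
#' @export
scene_object <- function(footprint, reflectors, label = c("non_plant", "plant"),
                         id = "obj") {
  label <- match.arg(label)
  footprint <- as.matrix(footprint)
  stopifnot(ncol(footprint) == 2, nrow(footprint) >= 3,
            all(is.finite(footprint)))
  structure(list(id = id, label = label, footprint = footprint,
                 reflectors = reflectors),
            class = "scene_object")
}

#' @rdname reflector
#' @param objects List of `scene_object`s.
#' @param bounds Axis-aligned rectangle `c(xmin, xmax, ymin, ymax)`, meters.
#' @param ground_truth_contours Optional named list of polylines (n x 2
#'   matrices) tracing the free-space-facing edges of the objects, e.g.
#'   `list(left = ..., right = ...)`.
#' @return `sonar_scene()`: a list of class `"sonar_scene"`.
#' @export
sonar_scene <- function(objects, bounds, ground_truth_contours = list()) {
  structure(list(objects = objects, bounds = bounds,
                 ground_truth_contours = ground_truth_contours),
            class = "sonar_scene")
}

#' Validate a scene against its type invariants
#'
#' Checks that footprints are simple polygons lying inside the scene bounds,
#' that every reflector has positive finite strength and lies on or inside
#' its object's footprint, and that contour polylines are finite.
#'
#' @param scene A [sonar_scene()].
#' @return The scene, invisibly; errors on violation.
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "sonar_scene"))
  b <- scene$bounds
  stopifnot(length(b) == 4, b[1] < b[2], b[3] < b[4])
  for (obj in scene$objects) {
    fp <- obj$footprint
    if (any(fp[, 1] < b[1] - 1e-9) || any(fp[, 1] > b[2] + 1e-9) ||
        any(fp[, 2] < b[3] - 1e-9) || any(fp[, 2] > b[4] + 1e-9))
      stop("object ", obj$id, ": footprint outside scene bounds")
    if (polygon_self_intersects(fp))
      stop("object ", obj$id, ": self-intersecting footprint")
    r <- obj$reflectors
    if (nrow(r)) {
      stopifnot(all(is.finite(r$x)), all(is.finite(r$y)),
                all(r$strength > 0), all(r$strength <= 1))
      inside <- point_in_polygon(r$x, r$y, fp, tol = 1e-6)
      if (!all(inside))
        stop("object ", obj$id, ": reflector outside footprint")
    }
  }
  for (ct in scene$ground_truth_contours)
    stopifnot(is.matrix(ct), ncol(ct) == 2, all(is.finite(ct)))
  invisible(scene)
}

# Even-odd point-in-polygon test with a boundary tolerance (points within
# tol of an edge count as inside).
point_in_polygon <- function(px, py, poly, tol = 0) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    io <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        if (x < xint) io <- !io
      }
      j <- i
    }
    if (!io && tol > 0) {
      d <- point_to_polyline_dist(x, y, rbind(poly, poly[1, , drop = FALSE]))
      if (d <= tol) io <- TRUE
    }
    inside[k] <- io
  }
  inside
}

# Distance from one point to a polyline given as an n x 2 matrix.
point_to_polyline_dist <- function(x, y, line) {
  n <- nrow(line)
  if (n == 1) return(sqrt((x - line[1, 1])^2 + (y - line[1, 2])^2))
  ax <- line[-n, 1]; ay <- line[-n, 2]
  bx <- line[-1, 1]; by <- line[-1, 2]
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ((x - ax) * vx + (y - ay) * vy) / pmax(L2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2))
}

# Crude O(n^2) segment-intersection check for simple-polygon validation;
# footprints are small so this is never a bottleneck.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]))
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Regular polygon approximating a circle, used for footprints.
circle_polygon <- function(center, radius, n = 24) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}

#' Single-reflector calibration scene
#'
#' One specular reflector at polar position (`range_m`, `azimuth_deg`)
#' relative to a robot at the origin facing +x, the layout used to estimate
#' localization accuracy with a lone cylindrical target.
#'
#' @param range_m Target range in meters, in `[0.2, 6]`.
#' @param azimuth_deg Target azimuth in degrees (positive left), `|az| <= 60`.
#' @param strength Reflection gain.
#' @return A [sonar_scene()] with one object carrying one reflector.
#' @export
#' @examples
#' sc <- make_single_reflector_scene(1, 0)
#' sc$objects[[1]]$reflectors[, c("x", "y")]   # (1, 0)
make_single_reflector_scene <- function(range_m, azimuth_deg, strength = 0.8) {
  if (range_m < 0.2 || range_m > 6) stop("range_m must be in [0.2, 6]")
  if (abs(azimuth_deg) > 60) stop("|azimuth_deg| must be <= 60")
  a <- azimuth_deg * pi / 180
  p <- c(range_m * cos(a), range_m * sin(a))
  obj <- scene_object(circle_polygon(p, 0.05), reflector(p, strength),
                      label = "non_plant", id = "target")
  sc <- sonar_scene(list(obj), bounds = c(-1, 8, -7, 7))
  validate_scene(sc)
  sc
}

#' Corridor scene with reflector walls
#'
#' Two straight walls of regularly spaced reflectors flanking a free path
#' along +x, a synthetic stand-in for a greenhouse trail. The corridor is
#' centered on y = 0 and starts at x = 0. Ground-truth contours are the two
#' wall lines (the free-space-facing edges). Optionally a cylindrical
#' obstacle is placed on the centerline.
#'
#' @param length_m Corridor length (>= 5 m).
#' @param width_m Free-path width between the walls (>= 2 m).
#' @param reflector_spacing_m Spacing of wall reflectors (0.1 to 1 m).
#' @param obstacle Optional `c(x, y)` center of a cylindrical obstacle.
#' @param obstacle_diameter_m Obstacle diameter, default 0.8 m.
#' @param wall_strength Reflection-gain interval of wall reflectors; each
#'   reflector draws its strength uniformly from it (deterministic given
#'   `seed`). Vegetation and trail borders reflect with widely varying
#'   strength; constant-gain walls would make every analysis window a
#'   worst-case tie between competing arrivals.
#' @param jitter_frac Wall reflectors are displaced along the wall line by
#'   uniform jitter of up to this fraction of the spacing (independently per
#'   wall, deterministic given `seed`). Real trail borders are irregular; a
#'   perfectly mirror-symmetric corridor is acoustically degenerate — every
#'   opposite reflector pair is exactly equidistant, so their echoes fuse
#'   into phantom arrivals with zero interaural delay, ghosts on the
#'   centerline that no real environment produces.
#' @param seed Integer seed for the jitter.
#' @return A [sonar_scene()] with `ground_truth_contours$left` (y > 0 wall)
#'   and `$right` (y < 0 wall); reflectors lie exactly on the contour lines.
#' @export
make_corridor_scene <- function(length_m, width_m, reflector_spacing_m,
                                obstacle = NULL, obstacle_diameter_m = 0.8,
                                wall_strength = c(0.15, 1.0),
                                jitter_frac = 0.45, seed = 0L) {
  if (length_m < 5) stop("length_m must be >= 5")
  if (width_m < 2) stop("width_m must be >= 2")
  if (reflector_spacing_m < 0.1 || reflector_spacing_m > 1)
    stop("reflector_spacing_m must be in [0.1, 1]")
  half <- width_m / 2
  if (length(wall_strength) == 1) wall_strength <- rep(wall_strength, 2)
  xs <- seq(0, length_m, by = reflector_spacing_m)
  wall <- function(ysign, id) {
    y <- ysign * half
    draws <- with_seed(derive_seed(seed, id), {
      j <- stats::runif(length(xs), -jitter_frac, jitter_frac) *
        reflector_spacing_m
      s <- stats::runif(length(xs), wall_strength[1], wall_strength[2])
      list(x = pmin(pmax(xs + j, 0), length_m), s = s)
    })
    refl <- do.call(rbind, lapply(seq_along(xs), function(k)
      reflector(c(draws$x[k], y), draws$s[k], "specular")))
    depth <- 0.3  # wall thickness away from the free path
    fp <- rbind(c(0, y), c(length_m, y),
                c(length_m, y + ysign * depth), c(0, y + ysign * depth))
    scene_object(fp, refl, label = "non_plant", id = id)
  }
  objects <- list(wall(+1, "wall_left"), wall(-1, "wall_right"))
  if (!is.null(obstacle)) {
    r <- obstacle_diameter_m / 2
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    refl <- do.call(rbind, lapply(ang, function(a)
      reflector(obstacle + r * c(cos(a), sin(a)), max(wall_strength),
                "specular")))
    objects <- c(objects, list(scene_object(circle_polygon(obstacle, r),
                                            refl, "non_plant", "obstacle")))
  }
  contours <- list(
    left = cbind(c(0, length_m), c(half, half)),
    right = cbind(c(0, length_m), c(-half, -half)))
  sc <- sonar_scene(objects,
                    bounds = c(-2, length_m + 2, -half - 1, half + 1),
                    ground_truth_contours = contours)
  validate_scene(sc)
  sc
}

#' Synthetic plant / non-plant object population
#'
#' Generates labeled objects for echo classification experiments, emulating
#' the acoustic contrast between vegetation and artificial obstacles:
#' a `plant` is a cluster of many weak `diffuse_member` scatterers (a
#' diffusive echo train); a `non_plant` is one to three strong `specular`
#' reflectors on a smooth footprint (a glint echo). Deterministic given
#' `seed`.
#'
#' @param n_per_class Objects per class (>= 1).
#' @param seed Integer seed.
#' @return A list of `scene_object`s, length `2 * n_per_class`, labels in
#'   the `label` field.
#' @export
make_object_echo_population <- function(n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    plants <- lapply(seq_len(n_per_class), function(i) {
      radius <- runif(1, 0.25, 0.5)
      n_ref <- sample(12:30, 1)
      rr <- 0.95 * radius * sqrt(runif(n_ref))  # stay inside the polygonal rim
      aa <- runif(n_ref, 0, 2 * pi)
      refl <- data.frame(x = rr * cos(aa), y = rr * sin(aa),
                         strength = runif(n_ref, 0.03, 0.15),
                         kind = "diffuse_member", stringsAsFactors = FALSE)
      scene_object(circle_polygon(c(0, 0), radius), refl, "plant",
                   sprintf("plant_%03d", i))
    })
    nonplants <- lapply(seq_len(n_per_class), function(i) {
      radius <- runif(1, 0.15, 0.4)
      n_ref <- sample(1:3, 1)
      rr <- radius * runif(n_ref, 0, 0.5)
      aa <- runif(n_ref, 0, 2 * pi)
      refl <- data.frame(x = rr * cos(aa), y = rr * sin(aa),
                         strength = runif(n_ref, 0.6, 1.0),
                         kind = "specular", stringsAsFactors = FALSE)
      scene_object(circle_polygon(c(0, 0), radius), refl, "non_plant",
                   sprintf("nonplant_%03d", i))
    })
    c(plants, nonplants)
  })
}

#' Place a prototype object into a fresh scene
#'
#' Translates an object (as produced by [make_object_echo_population()],
#' which generates footprints around the origin) to polar position
#' (`range_m`, `azimuth_deg`) in front of a robot at the origin facing +x.
#'
#' @param object A `scene_object` centered at the origin.
#' @param range_m,azimuth_deg Polar placement of the object center.
#' @return A validated single-object [sonar_scene()].
#' @export
place_object_scene <- function(object, range_m, azimuth_deg) {
  a <- azimuth_deg * pi / 180
  p <- c(range_m * cos(a), range_m * sin(a))
  obj <- object
  obj$footprint <- sweep(obj$footprint, 2, p, "+")
  obj$reflectors$x <- obj$reflectors$x + p[1]
  obj$reflectors$y <- obj$reflectors$y + p[2]
  ext <- max(range_m, 1) + 2
  sc <- sonar_scene(list(obj), bounds = c(-ext, ext, -ext, ext))
  validate_scene(sc)
  sc
}

#' Read and write scenes as JSON
#'
#' Scenes serialize to a plain JSON schema with explicit units (meters
#' throughout): `bounds`, `objects[]` each with `id`, `label`, `footprint`
#' (vertex list) and `reflectors` (x, y, strength, kind), and optional
#' `ground_truth_contours`.
#'
#' @param scene A [sonar_scene()].
#' @param path File path.
#' @return `read_scene()` returns a validated [sonar_scene()];
#'   `write_scene()` returns `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  validate_scene(scene)
  obj_list <- lapply(scene$objects, function(o) list(
    id = o$id, label = o$label,
    footprint = unname(apply(o$footprint, 1, function(v) v, simplify = FALSE)),
    reflectors = lapply(seq_len(nrow(o$reflectors)), function(i) list(
      x = o$reflectors$x[i], y = o$reflectors$y[i],
      strength = o$reflectors$strength[i], kind = o$reflectors$kind[i]))))
  cts <- lapply(scene$ground_truth_contours, function(m)
    unname(apply(m, 1, function(v) v, simplify = FALSE)))
  jsonlite::write_json(list(units = "meters", bounds = scene$bounds,
                            objects = obj_list,
                            ground_truth_contours = cts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  j <- jsonlite::read_json(path)
  objects <- lapply(j$objects, function(o) {
    fp <- do.call(rbind, lapply(o$footprint, unlist))
    refl <- do.call(rbind, lapply(o$reflectors, function(r)
      data.frame(x = r$x, y = r$y, strength = r$strength, kind = r$kind,
                 stringsAsFactors = FALSE)))
    scene_object(fp, refl, o$label, o$id)
  })
  cts <- lapply(j$ground_truth_contours, function(m)
    do.call(rbind, lapply(m, unlist)))
  sc <- sonar_scene(objects, unlist(j$bounds), cts)
  validate_scene(sc)
  sc
}
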