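small_cfg <- run_config(grid_n = 200, seed = 1)

test_that("a detected object inflates to a 20x20-cell (1 m^2) square", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  obj <- data.frame(x = 2, y = 0.5, range_m = 2.06, azimuth_deg = 14)
  m2 <- insert_and_inflate(m, obj, c(0, 0, 0), small_cfg)
  expect_equal(sum(m2$grid), 400)
  expect_equal(sum(m2$grid) * small_cfg$resolution_m^2, 1.0)
  # empty object list leaves the map unchanged
  m3 <- insert_and_inflate(m2, obj[0, ], c(0, 0, 0), small_cfg)
  expect_identical(m3$grid, m2$grid)
  # detections beyond the grid edge are dropped with a warning
  expect_warning(insert_and_inflate(m, data.frame(x = 1e4, y = 0),
                                    c(0, 0, 0), small_cfg), "outside")
})

test_that("trajectory cells always stay free, even inside inflated squares", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  m <- mark_trajectory(m, c(0, 0), c(3, 0))
  obj <- data.frame(x = 1.5, y = 0)   # object centered on the path
  m <- insert_and_inflate(m, obj, c(0, 0, 0), small_cfg)
  expect_true(sum(m$grid) < 400)      # the path cut through the square
  expect_false(any(m$grid & m$trajectory_cells))
  m <- connect_inflated(m, 3)
  expect_false(any(m$grid & m$trajectory_cells))
})

test_that("closing joins nearby squares and leaves isolated ones bounded", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  # two inflated squares separated by one free cell column
  m <- insert_and_inflate(m, data.frame(x = 1.0, y = 0), c(0, 0, 0), small_cfg)
  m <- insert_and_inflate(m, data.frame(x = 2.05, y = 0), c(0, 0, 0), small_cfg)
  gap_before <- sum(m$grid)
  m3 <- connect_inflated(m, 3)
  expect_gt(sum(m3$grid), gap_before)      # the gap was interpolated
  # connectivity: flood fill from one square reaches the other
  lab <- EBImage::bwlabel(m3$grid * 1)
  expect_equal(max(lab), 1)
  # iterations = 0 is the identity
  expect_identical(connect_inflated(m, 0)$grid, m$grid)
  # an isolated square stays within one closing-kernel dilation of itself
  m1 <- occupancy_map(c(0, 0, 0), small_cfg)
  m1 <- insert_and_inflate(m1, data.frame(x = 1.0, y = 0), c(0, 0, 0),
                           small_cfg)
  m1c <- connect_inflated(m1, 3)
  expect_lte(sum(m1c$grid), 22 * 22)
})

test_that("map integration runs on the 5-step cadence", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  pend <- data.frame(x = 1, y = 0.4, pose_x = 0, pose_y = 0, pose_h = 0)
  for (s in 1:4) {
    up <- update_cycle(m, s, pend, small_cfg)
    expect_equal(sum(up$map$grid), 0)          # buffered, not integrated
    expect_equal(nrow(up$pending_objects), 1)
  }
  up <- update_cycle(m, 5, pend, small_cfg)
  expect_gt(sum(up$map$grid), 0)
  expect_equal(nrow(up$pending_objects), 0)
  # no detections: the map is untouched on the cadence step too
  up0 <- update_cycle(m, 5, pend[0, ], small_cfg)
  expect_identical(up0$map$grid, m$grid)
  # two batches over 10 steps equal sequential application
  pend2 <- data.frame(x = 2, y = -0.6, pose_x = 0.5, pose_y = 0, pose_h = 0)
  a <- update_cycle(m, 5, pend, small_cfg)
  a <- update_cycle(a$map, 10, pend2, small_cfg)
  b <- insert_and_inflate(m, pend, c(0, 0, 0), small_cfg)
  b <- connect_inflated(b, 3)
  b <- insert_and_inflate(b, pend2, c(0.5, 0, 0), small_cfg)
  b <- connect_inflated(b, 3)
  expect_identical(a$map$grid, b$grid)
})

test_that("occupied cells are never cleared except by the trajectory", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  m <- insert_and_inflate(m, data.frame(x = 1, y = 1), c(0, 0, 0), small_cfg)
  before <- m$grid
  m2 <- insert_and_inflate(m, data.frame(x = 3, y = -1), c(0, 0, 0), small_cfg)
  expect_true(all(m2$grid[before]))
  m3 <- connect_inflated(m2, 3)
  expect_true(all(m3$grid[before]))
})

test_that("contours trace the free-space-facing edges of the mapped objects", {
  m <- occupancy_map(c(0, 0, 0), small_cfg)
  m <- mark_trajectory(m, c(0, 0), c(4, 0))
  # a band of objects along y = +1.5 (robot frame = world frame here)
  for (x in seq(0.5, 3.5, by = 0.5))
    m <- insert_and_inflate(m, data.frame(x = x, y = 1.5), c(0, 0, 0),
                            small_cfg)
  ct <- extract_contour(m, "left")
  expect_gt(nrow(ct), 5)
  # the inflated squares extend 0.5 m from their centers: the facing edge
  # sits near y = 1.0
  expect_true(all(abs(ct[, 2] - 1.0) < 0.11))
  # the other side is empty and flagged
  ct_r <- extract_contour(m, "right")
  expect_equal(nrow(ct_r), 0)
  expect_true(isTRUE(attr(ct_r, "empty")))
})

test_that("maps are deterministic and export with a georeferencing sidecar", {
  build <- function() {
    m <- occupancy_map(c(0, 0, 0), small_cfg)
    m <- mark_trajectory(m, c(0, 0), c(2, 0))
    m <- insert_and_inflate(m, data.frame(x = 1, y = 1), c(0, 0, 0), small_cfg)
    connect_inflated(m, 3)
  }
  expect_identical(build()$grid, build()$grid)
  m <- build()
  png_path <- withr::local_tempfile(fileext = ".png")
  write_map(m, png_path)
  img <- png::readPNG(png_path)
  expect_equal(sum(img > 0.5), sum(m$grid))
  side <- jsonlite::read_json(sub("\\.png$", ".json", png_path))
  expect_equal(side$resolution, m$resolution)
  expect_equal(side$occupied_cells, sum(m$grid))
})
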