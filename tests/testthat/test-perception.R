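test_that("matched filtering compresses a clean chirp to a single zero-lag peak", {
  n <- 8750
  rec <- structure(list(left = c(test_chirp, numeric(n - 2500)),
                        right = c(test_chirp, numeric(n - 2500)),
                        sample_rate = 250e3, pose = c(0, 0, 0),
                        heading_offset = 0),
                   class = "binaural_recording")
  tr <- matched_filter(rec, test_chirp, test_cfg)
  expect_equal(tr$left$ref, which.max(tr$left$raw))
  expect_equal(tr$left$ref, 1)
  # the emission is blanked, so nothing remains to detect
  expect_equal(nrow(detect_peaks(tr$left, test_cfg)), 0)
  # degenerate input is rejected
  rec0 <- rec; rec0$left[] <- 0; rec0$right[] <- 0
  expect_error(matched_filter(rec0, test_chirp, test_cfg), "all-zero")
  expect_error(matched_filter(rec, rnorm(9000), test_cfg), "shorter")
})

test_that("an injected echo produces a correlation peak within a sample of its delay", {
  n <- 8750
  d <- 3011  # samples
  sig <- c(test_chirp, numeric(n - 2500))
  sig2 <- sig
  sig2[(d + 1):(d + 2500)] <- sig2[(d + 1):(d + 2500)] + 0.4 * test_chirp
  rec <- structure(list(left = sig2, right = sig2, sample_rate = 250e3,
                        pose = c(0, 0, 0), heading_offset = 0),
                   class = "binaural_recording")
  tr <- matched_filter(rec, test_chirp, test_cfg)
  pk <- detect_peaks(tr$left, test_cfg)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$lag * 250e3 - d), 1)
})

test_that("peak picking honors the 0.3 threshold and 2 ms separation", {
  # two echoes 1 ms apart: only the larger is kept
  tr <- fake_trace(c(0.010, 0.011), c(0.9, 0.6))
  pk <- detect_peaks(tr, test_cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, 0.9, tolerance = 1e-6)
  # amplitude 0.29 is below threshold
  pk <- detect_peaks(fake_trace(c(0.010), c(0.29)), test_cfg)
  expect_equal(nrow(pk), 0)
  # three echoes >= 2 ms apart, all >= 0.3: all three survive, sorted by lag
  pk <- detect_peaks(fake_trace(c(0.020, 0.010, 0.015), c(0.4, 0.8, 0.5)),
                     test_cfg)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$lag, sort(pk$lag))
})

test_that("interaural matching accepts identical echoes and drops single-ear ones", {
  tr_both <- list(left = fake_trace(0.012, 0.9),
                  right = fake_trace(0.012, 0.9))
  lp <- detect_peaks(tr_both$left, test_cfg)
  rp <- detect_peaks(tr_both$right, test_cfg)
  pairs <- match_interaural(lp, rp, tr_both, test_cfg)
  expect_equal(nrow(pairs), 1)
  expect_gt(pairs$pearson_r, 0.999)
  expect_lt(abs(pairs$left_lag - pairs$right_lag), 1e-6)
  # echo present only in the left ear: no pair, by design conservatism
  tr_one <- list(left = fake_trace(0.012, 0.9),
                 right = fake_trace(0.025, 0.9))
  pairs <- match_interaural(detect_peaks(tr_one$left, test_cfg),
                            detect_peaks(tr_one$right, test_cfg),
                            tr_one, test_cfg)
  expect_equal(nrow(pairs), 0)
  # two echoes close together, both ears seeing the same double-bump
  # structure: each left peak gets two right candidates inside the +/-1 ms
  # window and must pair with the nearest in lag (a finer peak-spacing
  # setting so both candidates survive peak picking)
  cfg_fine <- sonar_config(min_peak_distance_s = 0.0003)
  tr_two <- list(left = fake_trace(c(0.01200, 0.01245), c(0.9, 0.6)),
                 right = fake_trace(c(0.01195, 0.01240), c(0.9, 0.6)))
  pairs <- match_interaural(detect_peaks(tr_two$left, cfg_fine),
                            detect_peaks(tr_two$right, cfg_fine),
                            tr_two, cfg_fine)
  expect_equal(nrow(pairs), 2)
  first <- pairs[which.min(abs(pairs$left_lag - 0.01200)), ]
  expect_lt(abs(first$right_lag - 0.01195), 5e-5)
})

test_that("localization converts lags to range and azimuth as stated", {
  mk <- function(l, r) data.frame(left_lag = l, right_lag = r,
                                  left_amp = 1, right_amp = 1,
                                  pearson_r = 0.99)
  # equal lags: broadside
  d <- localize(mk(0.01, 0.01), test_cfg)
  expect_equal(d$azimuth_deg, 0)
  expect_equal(d$range_m, 343 * 0.01 / 2)
  expect_identical(d$T, "unknown")
  # lag difference of baseline / c: full 90-degree lateral
  itd <- test_cfg$ear_baseline / 343
  d <- localize(mk(0.01, 0.01 + itd), test_cfg)
  expect_equal(d$azimuth_deg, 90, tolerance = 1e-9)
  # the arcsine argument is clamped for noise-perturbed lags
  d <- localize(mk(0.01, 0.01 + 1.2 * itd), test_cfg)
  expect_equal(d$azimuth_deg, 90)
  # a mean lag at the window edge corresponds to ~6 m and is discarded
  expect_null(localize(mk(0.035, 0.035), test_cfg))
  expect_equal(343 * 0.035 / 2, 6.0, tolerance = 0.01)
})

test_that("the full chain recovers a single reflector and merges cross-heading duplicates", {
  # round-trip accuracy over random placements
  set.seed(77)
  n_ok <- 0
  for (k in 1:15) {
    r <- runif(1, 0.4, 2.8); az <- runif(1, -45, 45)
    sc <- make_single_reflector_scene(r, az)
    rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 400 + k)
    d <- process_acquisition(rec, test_chirp, test_cfg)
    expect_equal(nrow(d), 1)
    expect_lt(abs(d$range_m - r), 0.013)
    expect_lt(abs(d$azimuth_deg - az), 1.2)
    # no detection exists without an accepted interaural pair
    expect_true(all(d$C > test_cfg$pearson_threshold))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 15)
  # the same reflector seen from two headings collapses to one object
  sc <- make_single_reflector_scene(1.2, 30)
  recs <- lapply(c(-60, 0, 60), function(off)
    synthesize_echoes(sc, c(0, 0, 0), off, test_cfg, seed = 500 + off))
  d <- process_acquisition(recs, test_chirp, test_cfg)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$azimuth_deg - 30), 1.2)
})
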