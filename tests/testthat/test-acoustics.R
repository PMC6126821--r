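test_that("the emitted chirp is a 2500-sample unit-amplitude downsweep", {
  ch <- test_chirp
  expect_length(ch, test_cfg$sample_rate * test_cfg$chirp_duration)
  expect_lte(max(abs(ch)), 1)
  expect_gte(max(abs(ch)), 0.99)
  # instantaneous frequency: highest at onset, lowest at the end, matching
  # the 100 -> 20 kHz sweep (estimated from zero-crossing spacing)
  inst_freq <- function(x, fs) {
    zc <- which(diff(sign(x)) != 0)
    fs / (2 * mean(diff(zc)))
  }
  fs <- test_cfg$sample_rate
  f_head <- inst_freq(ch[200:450], fs)    # ~1.3 ms in: ~90 kHz
  f_tail <- inst_freq(ch[2050:2300], fs)  # ~8.7 ms in: ~30 kHz
  expect_equal(f_head, 100e3 - 8e6 * 1.3e-3, tolerance = 0.05)
  expect_equal(f_tail, 100e3 - 8e6 * 8.7e-3, tolerance = 0.05)
  # matched-filter identity: autocorrelation peaks at zero lag
  ac <- batsonar:::xcorr_nonneg(c(ch, numeric(100)), ch)
  expect_equal(which.max(abs(ac)), 1)
  # frequencies above Nyquist are rejected
  expect_error(sonar_config(f_start = 130e3), "Nyquist")
})

test_that("echo arrival times match the analytic two-way delay within a sample", {
  fs <- test_cfg$sample_rate
  for (r in c(0.5, 1.0, 2.7)) {
    sc <- make_single_reflector_scene(r, 0)
    rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 2)
    tr <- matched_filter(rec, test_chirp, test_cfg)
    pk <- detect_peaks(tr$left, test_cfg)
    expect_equal(nrow(pk), 1)
    # exact mouth -> reflector -> left-ear path
    ear <- c(0, test_cfg$ear_baseline / 2)
    d_ear <- sqrt((r - ear[1])^2 + ear[2]^2)
    tau <- (r + d_ear) / test_cfg$speed_of_sound
    expect_lt(abs(pk$lag - tau), 1 / fs)
  }
  # a reflector at 1.0 m broadside arrives near sample 1458 (2 m / 343 m/s)
  sc <- make_single_reflector_scene(1.0, 0)
  rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 2)
  tr <- matched_filter(rec, test_chirp, test_cfg)
  pk <- detect_peaks(tr$left, test_cfg)
  expect_lt(abs(pk$lag * fs - 1458), 1.5)
})

test_that("two-way spherical spreading loses 12 dB per range doubling", {
  raw_peak <- function(r) {
    sc <- make_single_reflector_scene(r, 0, strength = 0.5)
    cfg <- sonar_config(noise_snr_db = 60)  # near-noiseless for the law
    rec <- synthesize_echoes(sc, c(0, 0, 0), 0, cfg, seed = 3)
    tr <- matched_filter(rec, test_chirp, cfg)
    max(tr$left$raw[tr$left$blank_n:length(tr$left$raw)])
  }
  drop_db <- 20 * log10(raw_peak(1.2) / raw_peak(2.4))
  expect_equal(drop_db, 12, tolerance = 0.5)
})

test_that("reflectors beyond the recording window contribute nothing", {
  sc_far <- sonar_scene(list(scene_object(
    batsonar:::circle_polygon(c(7, 0), 0.05),
    reflector(c(7, 0), 1), "non_plant")), bounds = c(-1, 9, -2, 2))
  rec <- synthesize_echoes(sc_far, c(0, 0, 0), 0, test_cfg, seed = 4)
  d <- process_acquisition(rec, test_chirp, test_cfg)
  expect_equal(nrow(d), 0)
})

test_that("empty scenes give emission plus noise and no detections", {
  sc0 <- sonar_scene(list(), c(-1, 1, -1, 1))
  for (s in 1:5) {
    rec <- synthesize_echoes(sc0, c(0, 0, 0), 0, test_cfg, seed = s)
    expect_length(rec$left, 8750)
    d <- process_acquisition(rec, test_chirp, test_cfg)
    expect_equal(nrow(d), 0)
  }
})

test_that("synthesis is deterministic given the seed", {
  sc <- make_single_reflector_scene(1.5, 10)
  r1 <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 9)
  r2 <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 9)
  expect_identical(r1, r2)
  r3 <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 10)
  expect_false(identical(r1$left, r3$left))
})

test_that("summing the three headings is sample-wise superposition", {
  sc <- make_single_reflector_scene(1.5, 0)
  recs <- lapply(c(-60, 0, 60), function(off)
    synthesize_echoes(sc, c(0, 0, 0), off, test_cfg, seed = 20 + off))
  s <- sum_headings(recs)
  expect_equal(s$left, recs[[1]]$left + recs[[2]]$left + recs[[3]]$left)
  expect_identical(s$heading_offset, "summed")
  # a reflector visible only at -60 degrees survives in the sum
  sc_side <- make_single_reflector_scene(1.5, -60)
  recs2 <- lapply(c(-60, 0, 60), function(off)
    synthesize_echoes(sc_side, c(0, 0, 0), off, test_cfg, seed = 30 + off))
  s2 <- sum_headings(recs2)
  d <- process_acquisition(s2, test_chirp, test_cfg)
  expect_gte(nrow(d), 1)
  # mismatched poses are rejected
  bad <- recs
  bad[[2]]$pose <- c(5, 0, 0)
  expect_error(sum_headings(bad), "pose")
})

test_that("recordings round-trip through float32 WAV", {
  sc <- make_single_reflector_scene(1.0, 0)
  rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 1)
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, p1)
  back <- read_wav(p1)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$left, rec$left, tolerance = 1e-6)
  expect_equal(back$right, rec$right, tolerance = 1e-6)
  # float32 content is preserved bit-exactly across a second round trip
  write_wav(back, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
})
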