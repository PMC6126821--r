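test_that("band splitting yields six full-length signals with the right spectra", {
  sc <- make_single_reflector_scene(1.5, 0)
  rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 6)
  sigs <- band_split(rec, test_cfg)
  expect_length(sigs, 6)
  expect_true(all(lengths(sigs) == length(rec$left)))
  expect_setequal(names(sigs),
                  c("left_20_40", "left_40_60", "left_60_100",
                    "right_20_40", "right_40_60", "right_60_100"))
  # a pure 30 kHz tone (placed after the blanked transmit interval) lands
  # almost entirely in the 20-40 kHz band
  n <- 8750; fs <- 250e3
  tone <- numeric(n)
  tone[3501:6000] <- sin(2 * pi * 30e3 * (0:2499) / fs)
  rec_t <- structure(list(left = tone, right = tone, sample_rate = fs,
                          pose = c(0, 0, 0), heading_offset = 0),
                     class = "binaural_recording")
  st <- band_split(rec_t, test_cfg)
  e <- vapply(st[c("left_20_40", "left_40_60", "left_60_100")],
              function(x) sum(x^2), 0)
  expect_gt(e[1] / sum(e), 0.95)
  # zero in, zero out
  rec_0 <- rec_t; rec_0$left[] <- 0; rec_0$right[] <- 0
  expect_true(all(vapply(band_split(rec_0, test_cfg),
                         function(x) max(abs(x)), 0) < 1e-9))
})

test_that("each band signal yields exactly the documented 483 features", {
  x <- rnorm(8750)
  fv <- extract_features(x)
  expect_length(fv, 483)
  layout <- attr(fv, "layout")
  expect_equal(unname(layout),
               c(23L, 46L, 23L, 23L, 23L, 23L, 23L, 299L))
  expect_equal(sum(layout), 483L)
  # a constant nonzero signal never crosses zero
  fv_c <- extract_features(rep(0.5, 8750))
  zcr_idx <- seq(1, 483, by = 21)   # ZCR is the first feature per window
  expect_true(all(fv_c[zcr_idx] == 0))
  # all-zero signal: defined by convention as all-zero features
  expect_true(all(extract_features(numeric(8750)) == 0))
})

test_that("the ensemble has the fixed architecture and trains reproducibly", {
  ds <- cached("tiny_ds", function() make_echo_dataset(10, seed = 21, test_cfg))
  m1 <- train_ensemble(ds, seed = 5, epochs = 5)
  expect_length(m1$nets, 6)
  for (net in m1$nets) expect_equal(net$sizes, c(483, 105, 50, 6, 1))
  m2 <- train_ensemble(ds, seed = 5, epochs = 5)
  p1 <- predict_echo(m1, ds$features)
  p2 <- predict_echo(m2, ds$features)
  expect_identical(p1, p2)
  # a one-class dataset is rejected
  bad <- ds
  bad$labels <- factor(rep("plant", length(ds$labels)),
                       c("non_plant", "plant"))
  expect_error(train_ensemble(bad, seed = 1), "both classes")
})

test_that("the trained ensemble separates diffuse from glint echoes above chance", {
  ds <- cached("clf_ds", function() make_echo_dataset(40, seed = 31, test_cfg))
  idx <- seq_along(ds$labels)
  te <- c(29:40, 69:80)            # 12 per class held out
  tr <- setdiff(idx, te)
  train <- list(features = ds$features[tr, , ], labels = ds$labels[tr])
  test <- list(features = ds$features[te, , ], labels = ds$labels[te])
  model <- cached("clf_model", function()
    train_ensemble(train, seed = 13, epochs = 60))
  pred <- predict_echo(model, test$features)
  ba <- balanced_accuracy(pred$T, as.character(test$labels))
  expect_gt(ba, 0.5)
})

test_that("majority voting and its tie-break follow the stated rules", {
  feats <- array(rnorm(6 * 483), dim = c(1, 6, 483))
  # five plant votes against one
  p <- predict_echo(const_ensemble(c(0.9, 0.8, 0.7, 0.9, 0.6, 0.2)), feats)
  expect_identical(p$T, "plant")
  expect_equal(p$P, mean(c(0.9, 0.8, 0.7, 0.9, 0.6)), tolerance = 1e-6)
  # a 3-3 tie with mean sigmoid 0.6 goes to plant
  p <- predict_echo(const_ensemble(c(0.95, 0.9, 0.85, 0.4, 0.3, 0.2)), feats)
  expect_identical(p$T, "plant")
  # all sigmoids near zero: confident non-plant
  p <- predict_echo(const_ensemble(rep(0.02, 6)), feats)
  expect_identical(p$T, "non_plant")
  expect_gt(p$P, 0.9)
})

test_that("balanced accuracy is the mean of per-class recalls", {
  # the worked two-class table: 77 % and 58 % recalls average to 67.5 %
  labels <- c(rep("plant", 100), rep("non_plant", 100))
  preds <- c(rep("plant", 77), rep("non_plant", 23),
             rep("non_plant", 58), rep("plant", 42))
  expect_equal(balanced_accuracy(preds, labels), (0.77 + 0.58) / 2)
  expect_equal(balanced_accuracy(labels, labels), 1.0)
  # an all-plant predictor on a 90/10 imbalanced set scores exactly chance
  lab_imb <- c(rep("plant", 90), rep("non_plant", 10))
  expect_equal(balanced_accuracy(rep("plant", 100), lab_imb), 0.5)
  expect_error(balanced_accuracy(rep("plant", 3), rep("plant", 3)),
               "two classes")
})

test_that("objects at 3 m or farther are never classified", {
  model <- const_ensemble(rep(0.9, 6))
  sc <- make_single_reflector_scene(1.0, 0)
  rec <- synthesize_echoes(sc, c(0, 0, 0), 0, test_cfg, seed = 2)
  near <- data.frame(range_m = 2.0, azimuth_deg = 0, T = "unknown", P = 0)
  far <- data.frame(range_m = 3.5, azimuth_deg = 0, T = "unknown", P = 0)
  out_near <- classify_detection(near, model, rec, run_config())
  out_far <- classify_detection(far, model, rec, run_config())
  expect_identical(out_near$T, "plant")
  expect_identical(out_far$T, "unknown")
  expect_equal(out_far$P, 0)
})

test_that("the permutation machinery validates input and the dead-end rule decides", {
  expect_error(permutation_test(list(), list(), 0.7, n_perm = 0), "positive")
  cand <- data.frame(direction = c("right", "ahead", "left"),
                     T = c("non_plant", "plant", "non_plant"),
                     P = c(0.9, 0.7, 0.8))
  expect_identical(dead_end_decision(cand), "ahead")
  cand$T <- "non_plant"
  expect_identical(dead_end_decision(cand), "boxed_in")
  cand$T <- c("plant", "non_plant", "plant")
  cand$P <- c(0.9, 0.95, 0.6)
  expect_identical(dead_end_decision(cand), "right")
})
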