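#' Matched-filter a binaural recording against the emitted chirp
#'
#' Cross-correlates each channel with the theoretical emitted signal (the
#' matched filter for delay estimation) and extracts the correlation
#' envelope via the analytic signal. The emission reference lag is the
#' earliest envelope peak within a factor two of the global maximum (the
#' direct emission is the first and loudest peak, at lag 0 in this
#' simulator). A short guard interval after the reference
#' (`config$blank_after_s`) is blanked; the post-blanking envelope is then
#' normalized by the larger of its own maximum and a noise detectability
#' floor (`noise_floor_k` robust sigmas), so that the 0.3 detection
#' threshold applies to echoes and pure noise yields no detections.
#'
#' @param recording A `binaural_recording`.
#' @param chirp The emitted template from [generate_chirp()].
#' @param config A [sonar_config()].
#' @return A list of class `"correlation_traces"` with elements `left` and
#'   `right`, each a list: `env` (normalized envelope over lags),
#'   `raw` (unnormalized envelope), `lag_s` (lag axis in seconds relative to
#'   the emission reference), `blank_n` (samples blanked), `norm` (the
#'   divisor used), `sample_rate`.
#' @export
matched_filter <- function(recording, chirp, config = sonar_config()) {
  if (all(recording$left == 0) && all(recording$right == 0))
    stop("all-zero recording")
  if (length(chirp) >= length(recording$left))
    stop("chirp must be shorter than the recording")
  fs <- recording$sample_rate
  traces <- lapply(list(left = recording$left, right = recording$right),
                   function(x) mf_one_channel(x, chirp, fs, config))
  structure(traces, class = "correlation_traces")
}

mf_one_channel <- function(x, chirp, fs, config) {
  # envelope computed on the full zero-padded correlation so the circular
  # Hilbert transform cannot leak the emission peak into the trace end
  env <- xcorr_envelope(x, chirp)
  # emission reference: earliest peak within 2x of the loudest
  ref <- which(env >= max(env) / 2)[1]
  blank_n <- ref + round(config$blank_after_s * fs)
  post <- env
  post[seq_len(min(blank_n, length(env)))] <- 0
  sigma <- stats::median(abs(post[post > 0])) / 0.6745
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-300
  # detectability floor: a noise-statistics gate plus an absolute gate
  # relative to the emission peak, so that neither noise extremes nor the
  # residual pulse-compression skirt of the emission register as echoes
  norm <- max(max(post), config$noise_floor_k * sigma,
              1e-3 * env[ref])
  list(env = post / norm, raw = env,
       lag_s = (seq_along(env) - ref) / fs,
       ref = ref, blank_n = blank_n, norm = norm, sample_rate = fs)
}

# Cross-correlation at non-negative template shifts:
# c[k+1] = sum_n x[n + k] * m[n], k = 0 .. N-1 (FFT-based).
xcorr_nonneg <- function(x, m) {
  n <- length(x)
  L <- stats::nextn(n + length(m), 2)
  X <- stats::fft(c(x, numeric(L - n)))
  M <- stats::fft(c(m, numeric(L - length(m))))
  full <- Re(stats::fft(X * Conj(M), inverse = TRUE)) / L
  full[seq_len(n)]
}

# Envelope of the cross-correlation over non-negative lags, computed on the
# full zero-padded sequence to keep the circular analytic-signal transform
# from wrapping energy between the trace ends.
xcorr_envelope <- function(x, m) {
  n <- length(x)
  L <- stats::nextn(n + length(m), 2)
  X <- stats::fft(c(x, numeric(L - n)))
  M <- stats::fft(c(m, numeric(L - length(m))))
  full <- Re(stats::fft(X * Conj(M), inverse = TRUE)) / L
  envelope(full)[seq_len(n)]
}

# Envelope by analytic signal (FFT Hilbert transform).
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Parabolic sub-sample refinement of a peak index on a sampled curve.
refine_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(0)
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(d, 0.5), -0.5)
}

#' Detect echo peaks on a normalized correlation trace
#'
#' Local maxima of the normalized correlation envelope with minimum
#' amplitude `peak_threshold` (0.3) and minimum separation
#' `min_peak_distance_s` (0.002 s), excluding the blanked emission
#' interval. Peak lags are refined to sub-sample precision by parabolic
#' interpolation. Peaks are returned sorted by lag.
#'
#' @param trace One channel of [matched_filter()] output (e.g. `$left`).
#' @param config A [sonar_config()].
#' @return A data.frame with columns `lag` (seconds, emission-referenced),
#'   `amplitude` (normalized, in `[0, 1]`), `idx` (sample index).
#' @export
detect_peaks <- function(trace, config = sonar_config()) {
  fs <- trace$sample_rate
  mpd <- max(1, round(config$min_peak_distance_s * fs))
  pk <- pracma::findpeaks(trace$env, minpeakheight = config$peak_threshold,
                          minpeakdistance = mpd)
  if (is.null(pk))
    return(data.frame(lag = numeric(0), amplitude = numeric(0),
                      idx = integer(0)))
  idx <- pk[, 2]
  lag <- (idx - trace$ref + vapply(idx, function(i) refine_peak(trace$env, i),
                                   0)) / fs
  out <- data.frame(lag = lag, amplitude = pk[, 1], idx = idx)
  out <- out[out$lag > 0, , drop = FALSE]
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match echo peaks across the two ears
#'
#' For each peak in the left (reference) ear, an equivalent peak is sought
#' in the right ear within +/- `match_window_s` (0.001 s) of its lag; among
#' candidates the nearest in lag is taken. A `segment_s` (0.01 s) segment of
#' the correlation envelope is cut around each ear's peak and the Pearson
#' correlation between the two segments computed; only pairs with
#' r > `pearson_threshold` (0.9) are accepted — deliberately conservative:
#' single-ear echoes are dropped rather than risking phantom objects. Each
#' right-ear peak is used at most once (left peaks processed in descending
#' amplitude).
#'
#' @param left_peaks,right_peaks Peak tables from [detect_peaks()].
#' @param traces The [matched_filter()] output the peaks came from.
#' @param config A [sonar_config()].
#' @return A data.frame with columns `left_lag`, `right_lag` (seconds),
#'   `left_amp`, `right_amp`, `pearson_r`.
#' @export
match_interaural <- function(left_peaks, right_peaks, traces,
                             config = sonar_config()) {
  empty <- data.frame(left_lag = numeric(0), right_lag = numeric(0),
                      left_amp = numeric(0), right_amp = numeric(0),
                      pearson_r = numeric(0))
  if (!nrow(left_peaks) || !nrow(right_peaks)) return(empty)
  fs <- traces$left$sample_rate
  half <- round(config$segment_s * fs / 2)
  used <- logical(nrow(right_peaks))
  rows <- list()
  for (i in order(-left_peaks$amplitude)) {
    dl <- abs(right_peaks$lag - left_peaks$lag[i])
    cand <- which(dl <= config$match_window_s & !used)
    if (!length(cand)) next
    j <- cand[which.min(dl[cand])]
    # Gaussian-weighted envelope segments centered on each ear's own peak
    # (sigma = segment/8): matched filtering compresses each echo to ~1/
    # bandwidth, so the weight concentrates the similarity test on the echo
    # being matched while unrelated arrivals farther out in the segment —
    # whose interaural alignment differs — are attenuated instead of
    # swamping the correlation
    w <- exp(-0.5 * (seq(-half, half) / (half / 4))^2)
    sl <- cut_segment(traces$left$env, left_peaks$idx[i], half) * w
    sr <- cut_segment(traces$right$env, right_peaks$idx[j], half) * w
    r <- suppressWarnings(stats::cor(sl, sr))
    if (is.finite(r) && r > config$pearson_threshold) {
      used[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        left_lag = left_peaks$lag[i], right_lag = right_peaks$lag[j],
        left_amp = left_peaks$amplitude[i],
        right_amp = right_peaks$amplitude[j], pearson_r = r)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$left_lag), , drop = FALSE]
}

cut_segment <- function(x, center, half) {
  i0 <- center - half; i1 <- center + half
  pad_l <- max(0, 1 - i0); pad_r <- max(0, i1 - length(x))
  c(numeric(pad_l), x[max(1, i0):min(length(x), i1)], numeric(pad_r))
}

#' Localize a matched interaural pair
#'
#' Converts an accepted pair of echo lags into a detected object: range
#' from the mean signal-to-echo delay, `range = c * mean(lags) / 2`; azimuth
#' from the interaural time difference,
#' `azimuth = asin(c * (right_lag - left_lag) / ear_baseline)` (positive to
#' the robot's left; the arcsine argument is clamped to `[-1, 1]` to survive
#' noise-perturbed lags). Pairs localizing beyond `max_range_m` are
#' discarded (`NULL`).
#'
#' @param pair One row of [match_interaural()] output.
#' @param config A [sonar_config()].
#' @return A one-row data.frame with columns `range_m`, `azimuth_deg`, `C`
#'   (the pair's Pearson r), `T` (`"unknown"` until classification), `P`
#'   (0 until classification); or `NULL` if out of range.
#' @export
localize <- function(pair, config = sonar_config()) {
  c_air <- config$speed_of_sound
  range_m <- c_air * mean(c(pair$left_lag, pair$right_lag)) / 2
  if (range_m > config$max_range_m || range_m <= 0) return(NULL)
  s <- c_air * (pair$right_lag - pair$left_lag) / config$ear_baseline
  s <- max(min(s, 1), -1)
  data.frame(range_m = range_m, azimuth_deg = asin(s) * 180 / pi,
             C = pair$pearson_r, T = "unknown", P = 0,
             stringsAsFactors = FALSE)
}

#' Full acquisition processing: detect, match, localize, merge
#'
#' Runs the complete perception chain on one acquisition: per recording,
#' matched filtering, peak detection in both ears, interaural matching and
#' localization; detections are rotated from the sensing frame into the
#' robot frame using each recording's heading offset, and duplicates closer
#' than `merge_radius_m` (10 cm) across headings are merged, keeping the
#' member with the highest interaural correlation. Multiple reflectors
#' within a single beam yield multiple detections as long as their echoes
#' are separable in delay.
#'
#' @param recordings A single `binaural_recording` or a list of them (the
#'   three-heading acquisition, or one summed recording).
#' @param chirp The emitted template.
#' @param config A [sonar_config()].
#' @return A data.frame of detected objects: `range_m`, `azimuth_deg`
#'   (robot frame), `x`, `y` (robot frame Cartesian), `C`, `T`, `P`,
#'   `heading_offset`.
#' @export
process_acquisition <- function(recordings, chirp, config = sonar_config()) {
  if (inherits(recordings, "binaural_recording")) recordings <- list(recordings)
  dets <- list()
  for (rec in recordings) {
    tr <- matched_filter(rec, chirp, config)
    lp <- detect_peaks(tr$left, config)
    rp <- detect_peaks(tr$right, config)
    pairs <- match_interaural(lp, rp, tr, config)
    off <- if (identical(rec$heading_offset, "summed")) 0
           else as.numeric(rec$heading_offset)
    for (k in seq_len(nrow(pairs))) {
      d <- localize(pairs[k, ], config)
      if (is.null(d)) next
      d$azimuth_deg <- d$azimuth_deg + off
      d$heading_offset <- rec$heading_offset
      dets[[length(dets) + 1]] <- d
    }
  }
  if (!length(dets))
    return(data.frame(range_m = numeric(0), azimuth_deg = numeric(0),
                      x = numeric(0), y = numeric(0), C = numeric(0),
                      T = character(0), P = numeric(0),
                      heading_offset = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, dets)
  a <- out$azimuth_deg * pi / 180
  out$x <- out$range_m * cos(a)
  out$y <- out$range_m * sin(a)
  merge_detections(out, config$merge_radius_m)
}

# Greedy duplicate merge: order by descending C; absorb every detection
# within radius of an already-kept one.
merge_detections <- function(dets, radius) {
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$C)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        min(sqrt((dets$x[keep] - dets$x[i])^2 +
                 (dets$y[keep] - dets$y[i])^2)) > radius)
      keep <- c(keep, i)
  }
  out <- dets[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
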