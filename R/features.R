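#' Split a recording into six band-limited signals
#'
#' Blanks the transmitted pulse (the first `chirp_duration` plus a 2 ms
#' guard of each channel) and passes each ear's signal through three
#' band-pass filters: 20-40 kHz, 40-60 kHz and 60-100 kHz (4th-order
#' Butterworth, zero-phase). Every echo is thus represented by
#' 6 signals = 3 bands x 2 ears, each the full recording length.
#'
#' @param recording A `binaural_recording`.
#' @param config A [sonar_config()].
#' @return A named list of six numeric vectors:
#'   `left_20_40, left_40_60, left_60_100, right_20_40, ...`.
#' @export
band_split <- function(recording, config = sonar_config()) {
  fs <- recording$sample_rate
  blank_n <- min(length(recording$left),
                 round((config$chirp_duration + 0.002) * fs))
  bands <- list(c(20e3, 40e3), c(40e3, 60e3), c(60e3, 100e3))
  out <- list()
  for (ear in c("left", "right")) {
    x <- recording[[ear]]
    x[seq_len(blank_n)] <- 0
    for (b in bands) {
      hi <- min(b[2], fs / 2 * 0.999)
      filt <- signal::butter(4, c(b[1], hi) / (fs / 2), type = "pass")
      nm <- sprintf("%s_%d_%d", ear, b[1] / 1e3, b[2] / 1e3)
      out[[nm]] <- as.numeric(signal::filtfilt(filt, x))
    }
  }
  out
}

#' Short-time acoustic feature vector of a band-limited echo
#'
#' The signal is divided into 23 half-overlapping windows (window length =
#' signal/12, hop = window/2) and 21 features are computed per window:
#' zero-crossing rate (1), short-time energy and energy entropy (2),
#' spectral entropy (1), spectral centroid (1), spectral spread (1),
#' spectral flux (1), spectral rolloff at 90 % (1), and a 12-bin
#' log-frequency chroma vector plus its deviation (13). Features are
#' concatenated window-major in a fixed order, giving 23 x 21 = 483 values.
#' Degenerate all-zero windows yield zeros by convention.
#'
#' @param x Numeric signal (one element of [band_split()] output).
#' @param sample_rate Samples per second.
#' @param n_windows Number of analysis windows (23).
#' @return Numeric vector of length 483 with attribute `layout`, the
#'   per-feature value counts (`feature_layout()`).
#' @export
extract_features <- function(x, sample_rate = 250e3, n_windows = 23) {
  stopifnot(length(x) > 0)
  win <- max(16, floor(length(x) / 12))
  hop <- floor(win / 2)
  feats <- matrix(0, n_windows, 21)
  prev_spec <- NULL
  for (w in seq_len(n_windows)) {
    i0 <- (w - 1) * hop + 1
    seg <- x[i0:min(i0 + win - 1, length(x))]
    if (length(seg) < win) seg <- c(seg, numeric(win - length(seg)))
    row <- window_features(seg, sample_rate, prev_spec)
    feats[w, ] <- row$values
    prev_spec <- row$spec
  }
  out <- as.numeric(t(feats))  # window-major, 21 features per window
  attr(out, "layout") <- feature_layout()
  out
}

#' @rdname extract_features
#' @return `feature_layout()`: named integer vector of total value counts
#'   per feature family over the 23 windows — ZCR 23, Energy 46 (short-time
#'   energy + energy entropy), Entropy 23, Spectral Centroid 23, Spectral
#'   Spread 23, Spectral Flux 23, Spectral Rolloff 23, Chroma Vector 299 —
#'   summing to 483.
#' @export
feature_layout <- function(n_windows = 23) {
  c(ZCR = 1L, Energy = 2L, Entropy = 1L, SpectralCentroid = 1L,
    SpectralSpread = 1L, SpectralFlux = 1L, SpectralRolloff = 1L,
    ChromaVector = 13L) * n_windows
}

# 21 features of one window. `prev_spec` is the previous window's
# normalized magnitude spectrum (for spectral flux; 0 for the first window).
window_features <- function(seg, fs, prev_spec = NULL) {
  n <- length(seg)
  zero <- list(values = numeric(21), spec = NULL)
  if (all(seg == 0)) {
    # convention for degenerate windows: all features 0
    return(zero)
  }
  # time-domain
  zcr <- sum(abs(diff(sign(seg))) > 0) / (n - 1)
  energy <- mean(seg^2)
  # energy entropy over 10 sub-blocks
  nb <- 10
  bl <- floor(n / nb)
  sub_e <- vapply(seq_len(nb), function(k)
    sum(seg[((k - 1) * bl + 1):(k * bl)]^2), 0)
  pe <- sub_e / max(sum(sub_e), 1e-300)
  energy_entropy <- -sum(ifelse(pe > 0, pe * log2(pe), 0))
  # spectrum (positive frequencies)
  spec <- Mod(stats::fft(seg))[seq_len(floor(n / 2))]
  freqs <- (seq_along(spec) - 1) * fs / n
  ps <- spec / max(sum(spec), 1e-300)
  spectral_entropy <- -sum(ifelse(ps > 0, ps * log2(ps), 0))
  centroid <- sum(freqs * ps) / (fs / 2)   # normalized to [0, 1]
  spread <- sqrt(sum((freqs - centroid * fs / 2)^2 * ps)) / (fs / 2)
  flux <- if (is.null(prev_spec)) 0 else sum((ps - prev_spec)^2)
  cum <- cumsum(spec^2) / max(sum(spec^2), 1e-300)
  rolloff <- freqs[which(cum >= 0.90)[1]] / (fs / 2)
  chroma <- chroma_vector(spec, freqs)
  list(values = c(zcr, energy, energy_entropy, spectral_entropy, centroid,
                  spread, flux, rolloff, chroma),
       spec = ps)
}

# 12-bin log-frequency chroma within the ultrasonic band plus deviation:
# bin energies folded by log2 frequency class relative to 20 kHz, then
# normalized; 13th value is the standard deviation of the 12 bins.
chroma_vector <- function(spec, freqs) {
  keep <- freqs > 0
  cls <- floor((log2(freqs[keep] / 20e3) %% 1) * 12) + 1
  e <- spec[keep]^2
  bins <- vapply(1:12, function(b) sum(e[cls == b]), 0)
  tot <- max(sum(bins), 1e-300)
  bins <- bins / tot
  c(bins, stats::sd(bins))
}

#' Features for a full binaural echo
#'
#' Convenience wrapper: [band_split()] then [extract_features()] per signal.
#'
#' @param recording A `binaural_recording`.
#' @param config A [sonar_config()].
#' @return A 6 x 483 matrix, rows named as in [band_split()].
#' @export
echo_features <- function(recording, config = sonar_config()) {
  sigs <- band_split(recording, config)
  t(vapply(sigs, function(s)
    as.numeric(extract_features(s, recording$sample_rate)), numeric(483)))
}
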