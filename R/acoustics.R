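#' Generate the emitted FM chirp
#'
#' A linear frequency-modulated downsweep from `f_start` to `f_end` over
#' `chirp_duration`, unit peak amplitude, sampled at `sample_rate`. With the
#' defaults this is the 10 ms, 100 to 20 kHz call used throughout: 2500
#' samples at 250 kS/s. The same waveform serves as the matched-filter
#' template.
#'
#' @param config A [sonar_config()].
#' @return Numeric vector of `sample_rate * chirp_duration` samples.
#' @export
#' @examples
#' length(generate_chirp(sonar_config()))  # 2500
generate_chirp <- function(config = sonar_config()) {
  validate_sonar_config(config)
  n <- round(config$sample_rate * config$chirp_duration)
  t <- (seq_len(n) - 1) / config$sample_rate
  chirp_wave(t, config)
}

# Continuous chirp waveform evaluated at arbitrary times (zero outside
# [0, chirp_duration)); exact fractional echo delays are synthesized by
# evaluating this closed form rather than resampling. A Tukey edge taper
# (config$chirp_taper) keeps the pulse-compression sidelobes of the loud
# direct emission far below any echo of interest.
chirp_wave <- function(t, config) {
  k <- (config$f_end - config$f_start) / config$chirp_duration
  inside <- t >= 0 & t < config$chirp_duration
  out <- numeric(length(t))
  ti <- t[inside]
  out[inside] <- sin(2 * pi * (config$f_start * ti + 0.5 * k * ti^2)) *
    tukey_window(ti / config$chirp_duration, config$chirp_taper)
  out
}

# Tukey (tapered-cosine) window evaluated at normalized positions u in [0,1).
tukey_window <- function(u, alpha) {
  if (alpha <= 0) return(rep(1, length(u)))
  w <- rep(1, length(u))
  lo <- u < alpha / 2
  hi <- u > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / alpha - 1)))
  w
}

# Ear positions for a sensor at `pos` pointing along heading `h_deg`
# (degrees CCW from +x): left ear offset +90 deg, right ear -90 deg.
ear_positions <- function(pos, h_deg, baseline) {
  h <- h_deg * pi / 180
  u <- c(-sin(h), cos(h)) * baseline / 2   # unit left, scaled
  list(left = pos + u, right = pos - u)
}

# Cosine-shaped beam gain: 1 on-axis, 0 at +/- halfwidth.
beam_gain <- function(az_deg, halfwidth_deg) {
  g <- cos(pi / 2 * az_deg / halfwidth_deg)
  ifelse(abs(az_deg) <= halfwidth_deg, pmax(g, 0), 0)
}

#' Synthesize a binaural echo recording from a scene
#'
#' Physics stand-in for the acquisition hardware. The emitter (mouth) sits
#' at the robot position, the two ears are spaced `ear_baseline` apart on an
#' axis perpendicular to the sensing heading (robot heading plus
#' `heading_offset`). For each reflector inside the beam, a delayed,
#' attenuated copy of the chirp is added to each channel with the exact
#' mouth-to-reflector-to-ear path delay; delays are fractional (the chirp is
#' evaluated in closed form), so arrival-time error is pure sampling
#' quantization. Attenuation is two-way spherical spreading
#' `1 / (r_out * r_back)`, clamped so no echo exceeds the emission level.
#' The direct emission appears at time 0 in both channels at unit amplitude.
#' White Gaussian noise is added at `noise_snr_db` below the strongest echo.
#'
#' @param scene A [sonar_scene()].
#' @param pose Robot pose `c(x, y, heading_deg)`.
#' @param heading_offset Acquisition heading offset in degrees, one of
#'   -60, 0, +60.
#' @param config A [sonar_config()].
#' @param seed Integer seed for the noise draw.
#' @return A `binaural_recording`: list with `left`, `right` (numeric
#'   sample vectors of `recording_duration * sample_rate` samples),
#'   `sample_rate`, `pose`, `heading_offset`.
#' @export
synthesize_echoes <- function(scene, pose, heading_offset = 0,
                              config = sonar_config(), seed = 1L) {
  validate_sonar_config(config)
  stopifnot(length(pose) == 3)
  if (!(heading_offset %in% c(-60, 0, 60)))
    stop("heading_offset must be one of -60, 0, 60")
  b <- scene$bounds
  if (pose[1] < b[1] || pose[1] > b[2] || pose[2] < b[3] || pose[2] > b[4])
    stop("pose outside scene bounds")
  n <- round(config$sample_rate * config$recording_duration)
  t <- (seq_len(n) - 1) / config$sample_rate
  h_sens <- pose[3] + heading_offset
  ears <- ear_positions(pose[1:2], h_sens, config$ear_baseline)
  left <- chirp_wave(t, config)   # direct emission, unit amplitude, t = 0
  right <- chirp_wave(t, config)
  refl <- scene_reflectors(scene)
  amp_max <- 0
  if (nrow(refl)) {
    dx <- refl$x - pose[1]; dy <- refl$y - pose[2]
    r_out <- sqrt(dx^2 + dy^2)
    az <- (atan2(dy, dx) * 180 / pi) - h_sens
    az <- ((az + 180) %% 360) - 180
    gain <- beam_gain(az, config$beam_halfwidth_deg)
    keep <- gain > 0 & r_out > 1e-6
    for (i in which(keep)) {
      for (ear in c("left", "right")) {
        e <- ears[[ear]]
        r_back <- sqrt((refl$x[i] - e[1])^2 + (refl$y[i] - e[2])^2)
        tau <- (r_out[i] + r_back) / config$speed_of_sound
        if (tau >= config$recording_duration) next  # beyond the window
        amp <- refl$strength[i] * gain[i] / max(r_out[i] * r_back, 1)
        amp_max <- max(amp_max, amp)
        w <- chirp_wave(t - tau, config)
        if (ear == "left") left <- left + amp * w else right <- right + amp * w
      }
    }
  }
  sigma <- max(amp_max * 10^(-config$noise_snr_db / 20), config$mic_noise_floor)
  with_seed(seed, {
    left <- left + rnorm(n, sd = sigma)
    right <- right + rnorm(n, sd = sigma)
  })
  structure(list(left = left, right = right,
                 sample_rate = config$sample_rate,
                 pose = pose, heading_offset = heading_offset),
            class = "binaural_recording")
}

# All reflectors of a scene as one data.frame.
scene_reflectors <- function(scene) {
  refl <- do.call(rbind, lapply(scene$objects, function(o) o$reflectors))
  if (is.null(refl))
    refl <- data.frame(x = numeric(0), y = numeric(0),
                       strength = numeric(0), kind = character(0))
  refl
}

#' Sum recordings from the three acquisition headings
#'
#' Superimposes the echoes returned from the -60, 0 and +60 degree headings
#' at one acquisition point into a single recording, emulating a much wider
#' emission beam at the cost of losing the per-heading separation. The
#' result carries `heading_offset = "summed"`.
#'
#' @param recordings List of three `binaural_recording`s from the same pose,
#'   one per heading offset (-60, 0, +60 in any order).
#' @return A `binaural_recording` with sample-wise summed channels.
#' @export
sum_headings <- function(recordings) {
  stopifnot(length(recordings) == 3)
  offs <- sort(vapply(recordings, function(r) as.numeric(r$heading_offset), 0))
  if (!isTRUE(all.equal(offs, c(-60, 0, 60))))
    stop("need one recording per heading offset -60, 0, +60")
  lens <- vapply(recordings, function(r) length(r$left), 0L)
  if (length(unique(lens)) != 1) stop("recordings have mismatched lengths")
  poses <- vapply(recordings, function(r) r$pose, numeric(3))
  if (max(apply(poses, 1, function(v) diff(range(v)))) > 1e-9)
    stop("recordings have mismatched poses")
  out <- recordings[[1]]
  out$left <- recordings[[1]]$left + recordings[[2]]$left + recordings[[3]]$left
  out$right <- recordings[[1]]$right + recordings[[2]]$right + recordings[[3]]$right
  out$heading_offset <- "summed"
  out
}

#' Write and read two-channel float32 WAV recordings
#'
#' Minimal RIFF/WAVE I/O for 2-channel IEEE float32 files at the sonar
#' sample rate; samples round-trip bit-exactly. Channel 1 is the left ear.
#'
#' @param recording A `binaural_recording`.
#' @param path File path.
#' @return `read_wav()` returns a `binaural_recording` (pose metadata is not
#'   stored in the WAV and comes back as zeros); `write_wav()` returns
#'   `path` invisibly.
#' @export
write_wav <- function(recording, path) {
  n <- length(recording$left)
  stopifnot(length(recording$right) == n)
  fs <- as.integer(recording$sample_rate)
  inter <- as.vector(rbind(recording$left, recording$right))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")       # IEEE float
  writeBin(2L, con, size = 2, endian = "little")       # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 8), con, size = 4, endian = "little")  # byte rate
  writeBin(8L, con, size = 2, endian = "little")       # block align
  writeBin(32L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(inter), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, integer(), size = 4)
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  fs <- NULL; fmt <- NULL; nchan <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nchan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      samples <- readBin(con, numeric(), n = sz / 4, size = 4,
                         endian = "little")
      break
    } else readBin(con, raw(), n = sz)
  }
  if (is.null(samples)) stop("no data chunk found")
  if (fmt != 3 || bits != 32) stop("only float32 WAV supported")
  if (nchan != 2) stop("expected 2 channels")
  m <- matrix(samples, nrow = 2)
  structure(list(left = m[1, ], right = m[2, ], sample_rate = fs,
                 pose = c(0, 0, 0), heading_offset = 0),
            class = "binaural_recording")
}
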