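#' Sonar hardware and signal-processing configuration
#'
#' Collects every constant of the sensing model in one validated object:
#' the emitted chirp, the sampling scheme, the binaural geometry, the
#' propagation model, and all detection thresholds. Defaults reproduce the
#' reference system: a 10 ms linear FM chirp sweeping 100 kHz down to
#' 20 kHz, sampled at 250 kS/s per ear, a 0.035 s recording window
#' (two-way range of about 6 m), and two ears 7 cm apart.
#'
#' @param chirp_duration Chirp length in seconds.
#' @param f_start,f_end Sweep start and end frequencies in Hz (downsweep by
#'   default). Both must be below Nyquist (`sample_rate / 2`).
#' @param sample_rate Samples per second per ear.
#' @param recording_duration Recording window length in seconds; must not be
#'   shorter than the chirp.
#' @param ear_baseline Distance between the two ears in meters.
#' @param speed_of_sound Speed of sound in m/s (343 m/s, air at 20 C).
#' @param beam_halfwidth_deg Half-width of the cosine-shaped emission beam in
#'   degrees; gain falls from 1 on-axis to 0 at the half-width.
#' @param noise_snr_db Additive white Gaussian noise level in dB relative to
#'   the strongest synthesized echo amplitude.
#' @param chirp_taper Tukey (cosine-taper) fraction applied to the chirp
#'   edges. Tapering is standard pulse-compression practice: it suppresses
#'   the correlation sidelobe skirt of the loud direct emission (about
#'   -100 dB re the peak beyond 1 ms with the default 0.25) which would
#'   otherwise masquerade as close-range echoes.
#' @param mic_noise_floor Receiver self-noise standard deviation relative to
#'   the unit emission amplitude; the additive noise never falls below this
#'   even for scenes with no or very weak reflectors.
#' @param peak_threshold Minimum normalized correlation amplitude for a peak
#'   to count as an echo (0.3).
#' @param min_peak_distance_s Minimum separation between detected peaks in
#'   seconds (0.002 s).
#' @param match_window_s Interaural search window for equivalent peaks in
#'   seconds (+/- 0.001 s).
#' @param segment_s Length of the segment cut around each peak for the
#'   interaural Pearson correlation (0.01 s).
#' @param pearson_threshold Minimum Pearson correlation for an interaural
#'   pair to be accepted (0.9).
#' @param blank_after_s Guard interval of correlation lag blanked after the
#'   emission reference peak, in seconds. Matched filtering compresses the
#'   emission to roughly the inverse bandwidth, so a short guard suffices;
#'   it sets the minimum detectable range (`c * blank_after_s / 2`).
#' @param noise_floor_k Detectability floor: the normalization divisor is at
#'   least `noise_floor_k` robust standard deviations of the post-blanking
#'   correlation envelope, so pure noise never produces peaks above
#'   `peak_threshold`.
#' @param max_range_m Detections beyond this range are discarded (the
#'   recording window itself limits range to about 6 m).
#' @param merge_radius_m Detections closer than this across headings are
#'   merged as one object.
#'
#' @return A validated list of class `"sonar_config"`.
#' @export
#' @examples
#' cfg <- sonar_config()
#' cfg$sample_rate * cfg$chirp_duration   # 2500 samples per chirp
sonar_config <- function(chirp_duration = 0.010,
                         f_start = 100e3,
                         f_end = 20e3,
                         sample_rate = 250e3,
                         recording_duration = 0.035,
                         ear_baseline = 0.07,
                         speed_of_sound = 343,
                         beam_halfwidth_deg = 60,
                         noise_snr_db = 20,
                         chirp_taper = 0.25,
                         mic_noise_floor = 1e-3,
                         peak_threshold = 0.3,
                         min_peak_distance_s = 0.002,
                         match_window_s = 0.001,
                         segment_s = 0.01,
                         pearson_threshold = 0.9,
                         blank_after_s = 0.001,
                         noise_floor_k = 15,
                         max_range_m = 6,
                         merge_radius_m = 0.10) {
  cfg <- list(
    chirp_duration = chirp_duration, f_start = f_start, f_end = f_end,
    sample_rate = sample_rate, recording_duration = recording_duration,
    ear_baseline = ear_baseline, speed_of_sound = speed_of_sound,
    beam_halfwidth_deg = beam_halfwidth_deg, noise_snr_db = noise_snr_db,
    chirp_taper = chirp_taper, mic_noise_floor = mic_noise_floor,
    peak_threshold = peak_threshold,
    min_peak_distance_s = min_peak_distance_s,
    match_window_s = match_window_s, segment_s = segment_s,
    pearson_threshold = pearson_threshold, blank_after_s = blank_after_s,
    noise_floor_k = noise_floor_k, max_range_m = max_range_m,
    merge_radius_m = merge_radius_m)
  class(cfg) <- "sonar_config"
  validate_sonar_config(cfg)
}

#' @rdname sonar_config
#' @param cfg A `sonar_config` object to validate.
#' @export
validate_sonar_config <- function(cfg) {
  stopifnot(inherits(cfg, "sonar_config"))
  nyq <- cfg$sample_rate / 2
  if (cfg$f_start > nyq || cfg$f_end > nyq)
    stop("chirp frequencies must not exceed Nyquist (", nyq, " Hz)")
  if (cfg$f_start <= 0 || cfg$f_end <= 0) stop("chirp frequencies must be positive")
  n_chirp <- cfg$sample_rate * cfg$chirp_duration
  if (abs(n_chirp - round(n_chirp)) > 1e-9)
    stop("sample_rate * chirp_duration must be an integer sample count")
  if (cfg$recording_duration < cfg$chirp_duration)
    stop("recording_duration must be >= chirp_duration")
  if (cfg$ear_baseline <= 0) stop("ear_baseline must be positive")
  if (cfg$speed_of_sound <= 0) stop("speed_of_sound must be positive")
  if (cfg$peak_threshold <= 0 || cfg$peak_threshold > 1)
    stop("peak_threshold must be in (0, 1]")
  cfg
}

#' Maximum unambiguous range of the recording window
#'
#' The two-way travel limit implied by the recording window:
#' `speed_of_sound * recording_duration / 2`. With the defaults,
#' 343 * 0.035 / 2 = 6.00 m, i.e. reflectors farther than about 6 m
#' cannot appear in the recording and are ignored.
#'
#' @param config A [sonar_config()].
#' @return Range in meters.
#' @export
max_recording_range <- function(config = sonar_config()) {
  config$speed_of_sound * config$recording_duration / 2
}

#' Full run configuration
#'
#' Bundles the sonar block with the navigation, mapping and classification
#' constants used by missions. Defaults are the reference system's values:
#' 0.5 m cruise steps, a 1.2 m frontal obstacle trigger over a +/-30 deg
#' sector, 1 m avoidance sidesteps, map integration every 5 steps, a
#' 2000x2000 grid of 5x5 cm cells with 20x20-cell (1 m^2) object inflation
#' and 3 closing iterations, and a 3 m classification gate.
#'
#' @param sonar A [sonar_config()].
#' @param step_m Cruise step length in meters.
#' @param obstacle_trigger_m Frontal obstacle distance that triggers
#'   avoidance, meters.
#' @param frontal_sector_deg Half-angle of the frontal sector considered
#'   "ahead", degrees.
#' @param sidestep_m Avoidance sidestep length, meters.
#' @param map_every_steps Map integration cadence in cruise steps.
#' @param grid_n Grid size (cells per side).
#' @param resolution_m Cell edge length, meters.
#' @param inflate_cells Side of the inflation square, cells.
#' @param closing_iterations Morphological closing passes per integration.
#' @param classify_max_range_m Objects beyond this range are never
#'   classified (their type stays unknown).
#' @param seed Master seed; fanned out to named sub-seeds per module.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sonar = sonar_config(),
                       step_m = 0.5,
                       obstacle_trigger_m = 1.2,
                       frontal_sector_deg = 30,
                       sidestep_m = 1.0,
                       map_every_steps = 5,
                       grid_n = 2000,
                       resolution_m = 0.05,
                       inflate_cells = 20,
                       closing_iterations = 3,
                       classify_max_range_m = 3,
                       seed = 1L) {
  stopifnot(inherits(sonar, "sonar_config"),
            step_m > 0, obstacle_trigger_m > 0, sidestep_m > 0,
            map_every_steps >= 1, grid_n >= 10, resolution_m > 0,
            inflate_cells >= 1, closing_iterations >= 0)
  structure(list(sonar = sonar, step_m = step_m,
                 obstacle_trigger_m = obstacle_trigger_m,
                 frontal_sector_deg = frontal_sector_deg,
                 sidestep_m = sidestep_m, map_every_steps = map_every_steps,
                 grid_n = grid_n, resolution_m = resolution_m,
                 inflate_cells = inflate_cells,
                 closing_iterations = closing_iterations,
                 classify_max_range_m = classify_max_range_m,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Derive a reproducible 32-bit sub-seed from a master seed and a label, so
# each randomness consumer (scene, noise, training, ...) is independently
# reproducible from one master seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
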