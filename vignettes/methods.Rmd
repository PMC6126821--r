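---
title: "Binaural bio-sonar simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binaural bio-sonar simulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`batsonar` is a desk-scale re-creation of a bat-like sensing stack: a single
ultrasonic emitter (the mouth) and two receivers (the ears, 7 cm apart)
mounted on a mobile agent that emits wide-band chirps, localizes reflectors
from the returning echoes, accumulates them into an occupancy map, steers
around obstacles reactively, and classifies echoes as vegetation-like or
not. This vignette records the models behind each stage, the parameters
that matter, and the choices we made where the design was genuinely open.

## The sensing model

**Emission.** The call is a linear FM downsweep, 100 kHz to 20 kHz over
10 ms, sampled at 250 kS/s, unit peak amplitude. A Tukey edge taper
(`chirp_taper = 0.25`) is applied. The taper matters for one quantitative
reason: the matched filter compresses the direct emission into a peak whose
pulse-compression sidelobe skirt, with a rectangular envelope, sits only
~50 dB below the peak out to several milliseconds of lag — comparable to a
weak echo. With the taper, the skirt falls below −100 dB beyond 1 ms and
never competes with echoes. The emitted waveform is evaluated in closed
form at arbitrary times, so synthesized echo delays are exact up to the
receiver's sampling, not quantized at synthesis.

**Propagation.** Each reflector in the beam contributes a delayed copy of
the chirp to each ear with delay `(r_out + r_back) / c`, where `r_out` is
the mouth-to-reflector distance and `r_back` the reflector-to-ear distance
(`c` = 343 m/s, 20 °C air, configurable). Amplitude follows two-way
spherical spreading `1/(r_out * r_back)`, scaled by the reflector strength
and the beam gain, and clamped at the emission level — the point-source
spreading law diverges in the extreme near field, and the clamp keeps the
direct emission the first and loudest arrival, which the emission-reference
logic relies on. Frequency-dependent atmospheric absorption is omitted:
over the ≤6 m ranges of interest it is a secondary correction. The direct
emission is injected at time zero in both ears at unit amplitude. White
Gaussian noise is added at `noise_snr_db` (default 20 dB) below the
strongest echo, with a floor of `mic_noise_floor` (10^-3 of the emission)
representing receiver self-noise.

**Beam.** The emission beam is cosine-shaped with configurable half-width:
gain 1 on axis, 0 at ±`beam_halfwidth_deg`. The default half-width is 60°,
a bat-like effective beam. The agent's acquisition protocol — three
emissions per stop, at −60°, 0° and +60° relative to the direction of
travel — exists to cover a wide field of view with a directional speaker,
so the mission fixtures use a 30° half-width speaker: three adjacent 60°
lobes tiling ±90°. The distinction matters most in summed-beam mode (below).

**Maximum range.** The 0.035 s recording window corresponds to
`343 × 0.035 / 2 ≈ 6 m` of two-way travel; reflectors farther than that
contribute nothing and detections beyond 6 m are discarded.

## The perception chain

Each channel is cross-correlated with the theoretical emitted signal (the
matched filter, optimal for delay estimation in white noise), and the
correlation envelope is taken via the analytic signal. The envelope is
computed on the full zero-padded correlation sequence: the FFT Hilbert
transform is circular, and on the truncated trace the enormous emission
peak at lag zero would leak into the opposite end of the lag axis.

**Emission reference and blanking.** The emission is identified as the
earliest envelope peak within a factor two of the global maximum; lags are
referenced to it. A 1 ms guard of lag after the reference is blanked.
Because pulse compression confines the emission to ~1/bandwidth (12.5 µs),
a short guard suffices; it sets the minimum detectable range at
`c × 1 ms / 2 ≈ 17 cm`. Blanking the full chirp duration instead would
erase every target closer than ~2 m, which the calibration experiments
(targets from 0.3 m) immediately rule out.

**Normalization and the detection floor.** The post-blanking envelope is
normalized by the larger of (a) its own maximum, (b) `noise_floor_k = 15`
robust standard deviations (median/0.6745) of the post-blanking envelope,
and (c) 10^-3 of the emission peak. The first term makes the 0.3 peak
threshold a relative criterion among echoes, as intended; the other two are
detectability floors without which a noise-only or echo-free trace would
normalize its own extremes to 1 and manufacture detections. A real echo
enjoys the matched filter's processing gain (~31× amplitude for this
time-bandwidth product) and clears both floors by orders of magnitude.

**Peak detection.** Local maxima of the normalized envelope with amplitude
≥ 0.3 and pairwise separation ≥ 2 ms, refined to sub-sample lag by
parabolic interpolation of the envelope around each peak.

**Interaural matching.** For every left-ear peak (the left ear is the
fixed reference), a right-ear peak is sought within ±1 ms; the nearest in
lag is taken, each right peak used at most once, left peaks processed in
descending amplitude. A 0.01 s segment of the correlation envelope is cut
around each ear's own peak and the Pearson correlation between the two
segments computed; the pair is accepted only if r > 0.9. Two
implementation choices here are ours:

* *Envelopes, not raw correlations.* The raw correlation oscillates at the
  ~60 kHz carrier (a 4-sample period); sub-sample interaural misalignment
  randomizes the carrier phase between the two segments and would make the
  0.9 threshold a coin flip. Envelopes are alignment-robust.
* *Gaussian segment weighting.* The segment is weighted by a Gaussian
  (σ = segment/8 ≈ 1.25 ms) centered on the peak. Matched filtering
  compresses each echo to ~12.5 µs, so the weight concentrates the
  similarity test on the echo being matched; unrelated arrivals farther
  out in the 10 ms segment — whose interaural alignment differs — attenuate
  instead of swamping the correlation. Without the weight, any scene with
  more than a few reflectors per beam fails the 0.9 gate everywhere and the
  robot goes blind; with it, the gate still rejects windows where competing
  arrivals of comparable strength sit within ~1 ms of the peak. The gate
  remains deliberately conservative: echoes are dropped rather than
  phantom objects created, so no detection ever exists without an accepted
  binaural pair.

**Localization.** Range is `c × mean(left lag, right lag) / 2`; azimuth is
`asin(c × (right lag − left lag) / baseline)`, positive to the robot's
left, the arcsine argument clamped to [−1, 1] against noise. With 4 µs
sampling the broadside azimuth quantization floor is
`asin(343 × 4e−6 / 0.07) ≈ 1.1°`; sub-sample peak refinement takes the
realized errors well below it. Detections from the three headings are
rotated into the robot frame by their heading offsets, and duplicates
within 10 cm are merged keeping the member with the highest interaural
correlation (consecutive emissions overlap heavily, so re-detections are
the norm; the merge radius is our choice).

## Synthetic scenes

The scene module is the stand-in for the field environments, and its
defaults are the study conditions for every test in the package.

* **Single-reflector scenes** reproduce the lab calibration: one specular
  target at a stated range and azimuth.
* **Corridor scenes** stand in for a greenhouse trail: two walls of point
  reflectors flanking a straight free path, with ground-truth contours on
  the wall lines. Two forms of irregularity are deliberate. Reflectors are
  jittered *along* the wall line (uniform, up to 45 % of the spacing) —
  a perfectly mirror-symmetric corridor is acoustically degenerate, since
  every opposite reflector pair is exactly equidistant and their echoes
  fuse into zero-ITD phantoms on the centerline, which no real trail
  produces. And reflector strengths draw uniformly from [0.15, 1] —
  natural borders reflect with widely varying strength, and constant-gain
  walls would make every analysis window a worst-case tie between
  competing arrivals. The jitter keeps reflectors exactly on the contour
  line, so the ground truth is unaffected. Wall spacing in the shipped
  fixtures is 0.5 m — discrete trunks and pots, not a continuous hedge.
* **Plant vs non-plant populations** encode the diffuse-versus-glint
  contrast: a plant is a cluster of 12–30 weak scatterers (strength
  0.03–0.15) across a 0.25–0.5 m canopy; a non-plant is 1–3 strong
  specular reflectors (strength 0.6–1) on a compact smooth footprint. The
  real sites' reflector statistics are unknown, so these densities are
  free parameters chosen once to be vegetation-plausible; they are not
  calibrated to any field site.

What the generator does *not* emulate: occlusion and multiple scattering,
frequency-dependent target signatures, reflector motion, and 3D structure.
Passing tests therefore demonstrate the processing chain's correctness and
its behavior under controlled clutter, not field performance.

## Mapping

Detections land on a world-fixed 2000×2000 grid of 5×5 cm cells (the
start pose at the center cell) and inflate to 20×20 cells — 1 m² — around
their cell: a detected point is treated as part of an object of roughly
that size, delineating clearance rather than geometry. Every 5 cruise
steps (2.5 m) the buffered detections are integrated and the map is passed
through 3 iterations of binary morphological closing with a 3×3 box
element, joining neighboring squares into continuous borders; closing is
the minimal standard operator with that behavior, and the iteration count
follows the three-pass design of the original inflation algorithm. Cells
the robot has traversed are forced free after every operation — an
observed open path outranks any inflated object. Contours are extracted
per side of the trail: boundary cells (occupied with a free 4-neighbor)
are assigned left/right by the sign of their lateral offset from the
trajectory, and the nearest boundary cell per 10 cm of arc length forms
the free-space-facing polyline.

Because inflation pushes each border half a meter toward the trail from
the detected point, corridor contour error is dominated by inflation
geometry (~0.5 m on the shipped fixtures) — the mapping resolution is far
coarser than the centimeter-level ranging accuracy, by design.

## Navigation

The agent cruises in 0.5 m steps, acquiring at each stop. An obstacle is
"ahead" when a detection from the most recent acquisition lies closer than
1.2 m within ±30° of the heading. The frontal sector is our choice (the
0° beam's neighborhood); the trigger consults the instantaneous
detections, not the integrated map — inflated cells extend 0.5 m beyond
each detected point, so a map-based reflex would see phantom blockage on
any trail narrower than the inflation (the map argument exists but is off
by default). Avoidance is the classic bug maneuver: turn 90° right,
sidestep 1 m when clear, turn back left and re-check; clear means resume
the pre-avoidance heading, blocked means keep sidestepping right. A
blocked sidestep rotates a further 90° right (wall-following fallback; the
degenerate corner case is not specified by the maneuver's description).
Collisions are checked along the entire swept segment at 5 cm resolution
and abort the mission with a full state dump. Odometry is assumed exact.

## Summed-beam mode

Summing the three headings' recordings into one superposition emulates a
single wide-beam emission. Two degradations follow from the physics of
the protocol, not from implementation: the ears rotate with the sensing
head, so each echo's interaural delay encodes the ear orientation *at its
own acquisition* — processing the sum with a single reference orientation
systematically compresses azimuths toward each beam's axis; and any
reflector illuminated by two overlapping beams arrives twice with two
different interaural geometries, scrambling the match. With the 30°
fixture speaker the second effect vanishes (adjacent lobes do not
overlap), and summed-mode mapping completes the corridor with sparse
detections and a contour error several times larger than the per-heading
mode — degraded but usable, which is the expected signature of trading
heading separation for a wide beam.

## Classification

Echoes are blanked of the transmit interval (chirp + 2 ms), band-passed
into 20–40, 40–60 and 60–100 kHz (4th-order zero-phase Butterworth), giving
6 signals = 3 bands × 2 ears. Each signal is cut into 23 half-overlapping
windows (window = signal/12, hop = window/2) and 21 features are computed
per window: zero-crossing rate; short-time energy and energy entropy;
spectral entropy, centroid, spread, flux, and 90 % rolloff; and a 12-bin
log-frequency chroma folded within the ultrasonic band plus its deviation.
That is 483 values per signal, and the per-family totals across windows
are 23/46/23/23/23/23/23/299. The 23-window layout is the only one
consistent with both the per-family totals and the 483-element input
layer; all-zero windows yield zero features by convention.

Six identical networks — one per band-ear signal — have the fixed
architecture 483 → 105 (ReLU) → dropout 0.5 → 50 (ReLU) → 6 (ReLU) → 1
(sigmoid). The training recipe is unconstrained by the architecture, so we
chose a standard one: z-scored inputs (training statistics stored in the
model), binary cross-entropy, Adam (lr 10^-3), batch 32, seeded; the
networks are small enough (~56k weights) that a plain matrix-algebra
implementation trains in seconds. Prediction is a majority vote of the
six sigmoids at 0.5, a 3–3 tie broken by the mean sigmoid, and the
reported probability is the mean sigmoid of the winning side's voters.
Objects at 3 m or beyond are never classified (their type stays unknown):
beyond that range the echo is too weak for the features to be meaningful.
Significance is assessed by retraining the full ensemble on label
permutations (default 100) and scoring each on the untouched test set;
the p-value is add-one smoothed, `(k+1)/(n+1)`. In a dead end with
obstacles right, ahead and left, the agent drives through the unique
plant, the highest-probability plant if several, and reports `boxed_in`
if none — vegetation is passable, masonry is not.

## Evaluation

Localization accuracy is measured on 100 single-reflector scenes (ranges
uniform 0.3–3 m, azimuths ±50°, 20 dB SNR, seeded) through the full
pipeline; the package reports mean ± SD of absolute range error (cm) and
absolute azimuth error (degrees). Contours under comparison are both
resampled at 500 arc-length-uniform points before scoring; the default
smoother is a parametric smoothing spline (x and y against normalized arc
length). A high-order polynomial fit — up to 55 coefficients per
coordinate, on an orthogonal basis, degree reduced automatically when the
basis is rank-deficient — is available behind `method = "polynomial"`: a
dense polynomial of that order is numerically treacherous, the RMS
comparison is insensitive to the smoother on smooth contours, and the
spline is the stable default. The error is the distance from each sampled
point of the estimated contour to the nearest point of the real one
(nearest-neighbor pairing; no correspondence is assumed), reported as
RMS, mean and SD over the 500 points.

## Problem sizes and reproducibility

The shipped test suite and examples run at desk scale, chosen once: 100
localization trials; 12 m corridors traversed in ≤40 steps; classifier
experiments with 60 objects per class (35 train / 25 test) at 40 epochs
and 100 label permutations. Every stochastic stage takes an explicit seed,
and a single master seed fans out to named per-module sub-seeds, so any
run directory is reproducible from its config snapshot and seed alone.

## Known limitations

Single-bounce propagation only (no occlusion, shadowing or multipath);
2D geometry with no elevation cues (the model has no external ear); exact
odometry; reactive navigation with no goal-directed planning or loop
closure; binary occupancy without uncertainty; and a classifier trained
and evaluated on synthetic diffuse-vs-glint contrasts — its accuracy
figures say nothing about any real vegetation corpus.
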