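# batsonar

Biomimetic binaural sonar, end to end: a desk-scale simulator and
processing pipeline for a bat-like sensing stack — one wide-band
ultrasonic emitter, two ears — mounted on an autonomous ground agent.
The package synthesizes two-channel chirp echoes from 2D virtual scenes,
then detects, matches, localizes, maps, classifies and navigates exactly
as such a robot does, and quantifies how well it did.

It is aimed at researchers in bio-sonar sensing, computational
neuroethology and robotics who want a controlled, fully reproducible
test bed for echo-based perception: every stage from the waveform to the
occupancy map is inspectable, seeded, and exercised by the test suite.

## The model in brief

The emitted call is a linear FM chirp, 100→20 kHz in 10 ms, sampled at
250 kS/s per ear; recordings are 0.035 s, i.e. a maximum two-way range of
`c·T/2 = 343 × 0.035 / 2 ≈ 6 m`. Each ear's signal is cross-correlated
with the emitted template (matched filter); peaks of the correlation
envelope above 0.3 (normalized), separated by ≥ 2 ms, are echo
candidates. A candidate in one ear is paired with one in the other within
±1 ms, accepted only if the Pearson correlation of 0.01 s envelope
segments exceeds 0.9 — conservative by design: objects may be missed, but
phantoms are not invented. An accepted pair localizes its reflector by

    range   = c · (τ_L + τ_R) / 4          (signal-to-echo delay)
    azimuth = arcsin( c · (τ_R − τ_L) / d )   (interaural time difference)

with ear baseline d = 0.07 m. Detections inflate to 1 m² squares on a
2000×2000 occupancy grid of 5 cm cells, connected by iterated
morphological closing every 5 steps of 0.5 m; the traversed path is
always free. Obstacle avoidance is the bug algorithm (turn 90° right
below 1.2 m, 1 m sidesteps, resume heading when clear). Echoes of
near objects (< 3 m) are classified plant / non-plant by an ensemble of
six small neural networks (one per frequency band and ear; input 483
short-time acoustic features) with majority voting, scored by balanced
accuracy against a 100-permutation label null.

## Worked example

Three reflectors inside a single beam, separated in range, resolved from
one binaural recording:

```r
library(batsonar)

cfg   <- sonar_config()            # all reference constants
chirp <- generate_chirp(cfg)       # 2500-sample FM template

sc <- sonar_scene(list(
  scene_object(batsonar:::circle_polygon(c(1.00,  0.00), 0.05),
               reflector(c(1.00,  0.00), 0.20), "non_plant", "a"),
  scene_object(batsonar:::circle_polygon(c(1.78,  0.25), 0.05),
               reflector(c(1.78,  0.25), 0.65), "non_plant", "b"),
  scene_object(batsonar:::circle_polygon(c(2.58, -0.36), 0.05),
               reflector(c(2.58, -0.36), 1.00), "non_plant", "c")),
  bounds = c(-1, 4, -2, 2))

rec <- synthesize_echoes(sc, pose = c(0, 0, 0), heading_offset = 0,
                         config = cfg, seed = 11)
process_acquisition(rec, chirp, cfg)[, c("range_m", "azimuth_deg", "C")]
#>    range_m  azimuth_deg         C
#> 1 1.000303 -0.008098736 0.9986105
#> 2 1.797637  7.997350287 0.9974024
#> 3 2.605105 -7.932961285 0.9973871
```

All three centers are recovered: ranges to ~3 mm, azimuths to well under
a tenth of a degree, each with an interaural correlation `C` far above
the 0.9 acceptance gate. The `T`/`P` columns (class and probability)
stay `unknown`/0 until a trained classifier annotates them.

A full autonomous mission, from the shell:

```sh
inst/cli/batsonar scene --length 10 --width 3 --spacing 0.5 --out scene.json
inst/cli/batsonar run   --scene scene.json --seed 4 --max-steps 20 --out rundir/
inst/cli/batsonar eval  --run rundir/ --scene scene.json --out report.json
```

`report.json` then contains the per-side contour errors of the acoustic
map against the scene's ground truth; on this corridor fixture the mean
error is ≈ 0.46 m (left) / 0.51 m (right) — dominated, as expected, by
the 1 m² object inflation, not by ranging error.

## Layout

```
R/                 scene, acoustics, perception, mapping, navigation,
                   classify (features + network ensemble), evaluation, io
inst/cli/batsonar  thin command-line front end (scene|synth|run|eval)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (models, parameters, design choices)
```
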