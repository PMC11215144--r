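# earcount

Count wheat ears (or any small, densely packed objects) in video from a
camera sweeping over a field, using tracking-by-detection: an external
detector proposes boxes per frame, a constant-velocity Kalman filter predicts
where each tracked ear will be next, the Hungarian algorithm matches
predictions to detections by IoU, and every track is counted exactly once —
at the moment its estimated centre crosses a baseline near the bottom of the
frame. Counting at a line instead of at first sight avoids double counts and
avoids counting partially visible ears at the frame edge.

The neural detector itself is out of scope: any model that emits boxes can
drive the counter, via detection tables (MOT-style CSV) or a plugged-in
detector function. A synthetic UAV-sweep simulator with a configurable noisy
detector channel stands in for real footage, so the whole pipeline is
testable end to end without any imagery.

## What's in the box

- **Geometry** — boxes as 2-D Gaussians, closed-form squared 2-Wasserstein
  distance, the Normalized Wasserstein Distance (NWD) similarity
  `exp(-W/C)` and its loss `1 - NWD`, which stays informative for tiny or
  disjoint boxes where IoU is exactly 0 (`nwd()`, `nwd_loss()`,
  `box_iou()`).
- **Space-to-depth** — the lossless downsampling rearrangement used by
  small-object detector backbones, with its exact inverse
  (`space_to_depth()`, `depth_to_space()`).
- **Kalman filter** — 8-D constant-velocity filter over
  `(cx, cy, w, h)` and their velocities (`kf_model()`, `kf_init()`,
  `kf_predict()`, `kf_update()`).
- **Assignment** — compiled Jonker–Volgenant solver for optimal one-to-one
  matching, with a strict IoU gate of 0.7 (`solve_assignment()`,
  `match_tracks()`).
- **Counter** — the per-frame predict–match–count–update loop
  (`count_ears()`, `step_tracks()`, `count_video()`).
- **Metrics** — precision/recall/F1/AP for detections, R²/RMSE for counts
  (`eval_detections()`, `eval_counts()`).
- **Simulator** — seeded synthetic sweeps with ground-truth boxes, expected
  crossing counts, and detector miss/jitter/false-positive noise
  (`simulate_scene()`, `corrupt_detections()`).
- **IO + CLI** — MOT-style CSV, LabelMe JSON, YAML config, and an
  `earcount` command with `simulate`, `count`, `eval-detect` and
  `eval-count` subcommands (`exec/earcount`, `earcount_cli()`).

Everything takes and returns tibbles, and result objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Quick start

```r
library(earcount)

# a synthetic sweep: 60 ears, 240 frames, 1280 x 720 px window
sc <- simulate_scene(scene_config(n_objects = 60, seed = 42))
sc
#> <wheat_scene> 60 objects, 240 frames (1280 x 720 px), expected count 44

# a 90%-recall detector with 1 px of jitter
dets <- corrupt_detections(sc, detect_prob = 0.9, jitter_sigma = 1)

res <- count_ears(dets, counter_config())
res
#> <ear_count> total = 44 counted over 240 frames (286 tracks)

glance(res)
#> # A tibble: 1 x 4
#>   total n_frames n_tracks mean_track_hits
#>   <int>    <int>    <int>           <dbl>
#> 1    44      240      286            21.4

# NWD vs IoU on a near-miss pair of small boxes
box_iou(bbox(10, 10, 4, 8), bbox(12, 11, 4, 8))
#> [1] 0.28
nwd(bbox(10, 10, 4, 8), bbox(12, 11, 4, 8))
#> [1] 0.8397149
```

`autoplot(sc)` draws the object trajectories against the counting baseline;
`autoplot(res)` draws the cumulative count curve.

### Command line

```sh
earcount simulate --seed 7 --detect-prob 0.9 --jitter-sigma 1 \
    --out-truth truth.csv --out-dets dets.csv
earcount count --detections dets.csv --out result.json
earcount eval-detect --pred dets.csv --truth truth.csv
earcount eval-count --pred counts_pred.csv --truth counts_true.csv
```

Every run logs a reproducibility header (package version, seed, config
hash); all randomness flows from the config seed.

### Real footage

Run your detector per frame and hand the boxes over either as a MOT CSV
(`frame, id, x, y, w, h, conf`, corner coordinates) through
`read_detections()`, or as a function:

```r
res <- count_video(frame_paths,
                   detector = function(frame, i) my_model(frame),
                   cfg = counter_config(frame_size = c(3840, 2160)))
```

## Testing and reproduction

```r
testthat::test_dir("tests/testthat")   # unit, property and acceptance tests
```

`tests/testthat/test-acceptance.R` holds the acceptance battery: closed-form
vs matrix-form geometry, space-to-depth bijection, Kalman filter vs an
independent matrix oracle, assignment vs brute-force permutation search,
exact count recovery on noiseless scenes, bounded degradation under heavy
detector noise, metric worked examples, and the end-to-end CLI pipeline.

A standalone report of the same quantities:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

With seed 1 this reports, among others, zero count error on 10 noiseless
scenes of 50–200 objects, a worst-case relative count error of 9.8% at
detection probability 0.7 with 2 px jitter, and R² = 0.999 between counted
and true ear numbers over 10 scenes at moderate noise.

The methods vignette (`vignettes/earcount-methods.Rmd`) derives the model,
documents every default, and discusses the design decisions and failure
modes — in particular why the tracker tolerates up to three missed frames
before dropping a track.
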