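# gridsight

3D localization of an intraoperative electrocorticography (ioECoG) electrode
grid from low-resolution stereo grayscale camera frames.

## The problem

During tailored epilepsy surgery an 8x8 grid of 4 mm electrode disks (5 mm
pitch) embedded in a flexible silicone sheet is placed on the exposed cortex
to map epileptic activity. Knowing each electrode's 3D position is what ties
the recorded signals to anatomy, yet at head-mounted-camera resolution
(640x480) and surgical working distance (40-90 cm) the whole grid spans only
22-60 pixels — single disks are a few pixels wide and the square electrode
pattern is 4-fold rotationally symmetric, so even a perfect detector cannot
number the electrodes without extra information.

`gridsight` implements the full pipeline for this regime, for stereo frames
from a calibrated rig or from its own synthetic renderer:

1. stereo **undistortion + rectification** (pinhole model, radial k1-k3 +
   tangential p1-p2 distortion, Fusiello-style rectifying rotations);
2. grid **detection** and cropping with exact coordinate bookkeeping
   (classical contrast/connected-component detector, oracle detector, or any
   external detector behind the same contract);
3. **x4 upscaling** of the small crop (deterministic bicubic, with a plug-in
   hook for a learned super-resolution model);
4. **2D pose**: difference-of-Gaussian disk-center candidates with subpixel
   refinement, cable ("tail") candidates, and assignment of candidates to
   physical electrode indices 1..64 by a robust projective fit of the
   canonical grid plane — the four tails resolve the 90-degree rotational
   ambiguity of the square lattice;
5. **triangulation** of the 68 ordered stereo correspondences
   (z = f·b/disparity in the rectified model);
6. the **relative-pose evaluation protocol**: a 30-position measurement grid
   over 40-90 cm and a 32x50 cm working area, a stereo acceptance rule
   (exactly one detection per view), a 10 cm median outlier filter with
   false-positive statistics, per-position mean/sd of the relative-pose
   error against the closest central reference position, and a normalized
   per-electrode 8x8 error heatmap.

The synthetic-scene module renders stereo frames of the (optionally
deformed) grid with randomized pose, lighting, background, blur and sensor
noise, and writes exact projected ground-truth labels — usable both for
exercising the pipeline and for generating multi-scale super-resolution
training corpora (90,000 base renders x scales {1, 0.75, 0.5, 0.33} =
360,000 images at full scale; any size runs locally).

## The statistic at the core

With the grid static at each measurement position, the pipeline measurement
`m` and ground truth `t` are compared through relative displacements from a
reference position (the closest central one, 40 cm):

    error_i = | ‖m_i(pos) − m_i(ref)‖ − ‖t_i(pos) − t_i(ref)‖ |

per electrode `i`, averaged over the 64 electrodes per frame, then over the
repeated frames per position. Rectified-stereo depth error propagates as
Δz ≈ z²·σ_d/(f·b) (σ_d = disparity noise), so the error grows with the
square of distance — the experiment harness reproduces exactly that shape.

## Electrode indexing convention

Electrodes are numbered row-major starting at the corner diagonally opposite
the tail edge; tails are indices 65-68:

        1  2  3  4  5  6  7  8
        9 10  .  .  .  .  . 16
        .  .              .  .
       49  .              . 56
       57 58  .  .  .  . 63 64
          |  |   |  |            <- 4 cables ("tails"), keypoints 65..68

## Worked example

```r
library(gridsight)

rig <- default_rig()          # 640x480, fx = 450 px, 98 mm baseline
rig$rectified <- TRUE         # ideal pinhole: rectification is the identity

# a flat grid facing the left camera at 40 cm, rendered with default noise
scene <- make_measurement_scenes(measurement_layout(depths = 0.40,
                                                    n_lateral = 1))[[1]]
pair <- render_stereo(rig, scene$state, render_settings(seed = 5))

# detect -> accept -> crop -> upscale x4 -> 2D pose, in each view
dl <- detect_grid(pair$left$image,  detector_config("classical"))
dr <- detect_grid(pair$right$image, detector_config("classical"))
acc <- accept_stereo(dl, dr)
kl <- estimate_pose_2d(pair$left$image,  acc$left)
kr <- estimate_pose_2d(pair$right$image, acc$right)

# triangulate the 68 ordered correspondences and compare with the truth
m <- triangulate_grid(rig, kl, kr)
err <- sqrt(rowSums((m$points3d - scene$state$points3d)^2))
summary(1000 * err[1:64])     # per-electrode 3D error, mm
```

which prints (seed 5):

```
   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
0.01795 0.12207 0.21522 0.24738 0.32946 0.73882
```

a mean 3D localization error of about 0.25 mm per electrode at 40 cm, with
all 68 keypoints found and correctly indexed. The full protocol is one call:

```r
report <- run_experiment(default_config(), seed = 1)   # ~4-5 min, 900 frames
report$per_position      # id, depth, mean/sd relative-pose error, counts
report$fp                # false-positive rate per depth band
report$heatmap           # normalized 8x8 per-electrode error map
```

In this replication the mean relative-pose error stays below 5 mm up to
60 cm and below 2 mm at 40 cm, grows to centimeter level beyond 80 cm, and
the median filter rejects nothing at 60 cm or closer — the qualitative and
quantitative behavior expected of the method in its operating range.

## Command-line interface

A thin CLI over the package functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gridsight", package="gridsight"))')" \
    run-experiment --seed 1 --out out/
# subcommands: simulate-corpus, simulate-experiment, run-experiment, fixtures
```

## Configuration

All parameters live in one YAML schema (see `default_config()`): rig
intrinsics/baseline/distortion, grid geometry, render appearance, detector /
upscaler / pose plugin blocks, and the experiment layout. Unknown keys are
rejected with the offending key named; units are meters and pixels
throughout. The vignette (`vignettes/grid-localization.Rmd`) documents the
model, the defaults and their rationale, and the package's limitations.
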