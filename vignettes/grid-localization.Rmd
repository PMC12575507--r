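---
title: "Localizing a deformable electrode grid from low-resolution stereo frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing a deformable electrode grid from low-resolution stereo frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridsight)
```

## The problem

During tailored epilepsy surgery an intraoperative electrocorticography
(ioECoG) grid — an 8x8 array of 4 mm conductive disks in a flexible silicone
sheet, 5 mm pitch — is placed on the exposed cortex, and the surgical team
needs to know where each of its 64 electrodes is in 3D. Head-mounted stereo
cameras are an attractive sensor for this because they are already in the
surgeon's line of sight, but at 640x480 resolution and 40–90 cm working
distance the whole grid spans only 22–60 pixels: individual disks cover a
handful of pixels and are barely distinguishable.

`gridsight` implements the full localization pipeline for this regime:

1. **Undistortion and rectification** of the stereo pair, so that
   corresponding points share a row and triangulation reduces to a 1D
   disparity (`undistort_rectify()`, `rectify_rig()`).
2. **Detection** of the grid and cropping with exact coordinate bookkeeping
   (`detect_grid()`, `crop_frame()`).
3. **Upscaling** of the small crop by a factor of four (`upscale()`;
   deterministic bicubic by default, with a plug-in hook for a learned
   super-resolution model).
4. **2D pose**: locating the 64 disk centers plus the 4 cable "tails" and
   assigning each detected center its physical electrode index
   (`detect_keypoint_candidates()`, `assign_indices()`).
5. **Triangulation** of the 68 stereo correspondences into 3D positions
   (`triangulate_grid()`).

Because the electrode pattern is a symmetric square, a 90° rotation of the
grid maps electrode positions onto electrode positions; without extra
information the wrong electrode numbers could be assigned. The four cables
leaving one edge of the sheet break that symmetry, and the pose stage uses
them to resolve the rotational ambiguity.

The package also contains the evaluation protocol used to quantify tracking
accuracy (`run_experiment()`), and a synthetic-scene renderer
(`render_stereo()`) that generates stereo frames with exact projected
ground-truth labels, standing in both for the physical cameras and for an
external 3D rendering pipeline when generating training corpora
(`make_sr_corpus()`).

## The virtual stereo rig

No public calibration exists for the head-mounted grayscale stereo cameras
this pipeline targets, so the package ships a documented virtual rig
(`default_rig()`): 640x480 sensors, 98 mm baseline, fronto-parallel, zero
distortion, and a 450 px focal length (about 71° horizontal field of view).
The focal length is pinned down by two published operating facts: the grid
should *just* fit inside both views at the closest working distance (40 cm)
when moved across a 32 cm wide working area, and grid crops should span
roughly 22–60 px across the 90–40 cm range. At fx = 450 the extreme lateral
40 cm position just fits in the right camera's view, and the crop-width band
comes out at about 22–60 px. All rig parameters are overridable through the
`rig` config block, and lens distortion (radial k1–k3 + tangential p1, p2)
is supported end to end: an ideal-pinhole mode is simply the all-zero
default, which is also the mode the experiment harness uses, since
rectification is then the identity and adds no resampling error of its own.

Pixel convention, used everywhere: 0-based coordinates, (0, 0) at the
*center* of the top-left pixel, +x right, +y down. Bounding boxes are
`(x_min, y_min, width, height)`. The world frame is the left (rectified)
camera frame, right-handed, +z forward — the relative-pose evaluation never
needs an absolute frame.

## Grid geometry and the deformation model

`canonical_grid()` places electrode `(r, c)` at `((c-1)·pitch, (r-1)·pitch, 0)`
in the grid frame; indexing is row-major from the corner diagonally opposite
the tail edge, so electrodes 57–64 form the row next to the cables. The four
tail keypoints sit one pitch apart, centered along that edge, one disk
diameter beyond it — one keypoint per cable. (Whether a physical labeling
would use one point per cable or several along each cable is a convention;
we model one per cable and the config accepts explicit `tail_offsets`.)

The silicone sheet bends but does not stretch, so `deform()` models
deformation as a composition of:

* a **cylindrical bend** (signed curvature + in-plane axis angle), which is
  exactly arc-length preserving, with a curvature bound of 20 m⁻¹ (bend
  radius ≥ 50 mm — tighter than any brain surface the sheet would rest on);
* a **smooth random height field**, a degree ≤ 3 polynomial in the sheet
  coordinates with coefficients drawn at a configured amplitude
  (≤ 2.5 mm), followed by Jacobi-style edge-length relaxation (120 sweeps,
  corrections averaged per vertex degree) pulling every nearest-neighbor
  distance back toward the pitch.

The guaranteed invariant, enforced by tests over random accepted parameters,
is *near-isometry*: all 112 nearest-neighbor electrode distances stay within
±2 % of the 5 mm pitch. Note one geometric subtlety: a bend preserves arc
length, so point-to-point *chords* are slightly shorter than the pitch
(2R·sin(p/2R) ≈ 0.5 µm shorter at R = 100 mm) — the invariant is about that
scale of deviation, not exact equality.

## The renderer and what it does (not) emulate

`render_stereo()` rasterizes the projected sheet polygon, per-electrode
disks (as the affine image of each disk under the local tangent-plane
projection, i.e. correct ellipses to first order) and cable segments, with
4x supersampled anti-aliasing, Lambertian-style shading under a directional
light plus ambient term, Gaussian optical blur, and additive Gaussian sensor
noise. Keypoint labels are the *exact projections* of the 3D disk centers —
never measured back from pixels — which is what makes the renderer usable as
a label generator for training corpora (`make_sr_corpus()` writes
image + label pairs in the normalized single-line label format that
single-stage pose detectors train on).

Default appearance values (all on a [0, 1] intensity scale): background
0.10–0.30 (flat, gradient or textured-noise), sheet 0.45 ± 0.02, disks
0.85 ± 0.02, cables 0.75, blur σ = 0.7 px, sensor noise σ = 0.02. These
produce the contrast ordering background < sheet < cables < disks that the
classical detector and pose stage rely on, and noise/blur levels at which
disk centers are localizable to a fraction of a pixel at 40 cm but
measurably degrade beyond 60 cm — the operating regime the method is
designed for.

What the renderer deliberately does **not** model: photorealistic tissue
appearance and specularity, occlusion of electrodes by the skull edge,
head-mounted-display motion blur, and shadows. Pipeline results on these
synthetic scenes therefore demonstrate the geometric and algorithmic
behavior of the method (indexing, symmetry breaking, triangulation error
versus distance), not its appearance robustness on real operative imagery —
a trained detector and pose model, plugged in through the `external` hooks,
would carry that burden.

## The classical pose path

The trained 2D pose network this pipeline was designed around is replaced,
at desk scale, by a classical path with the same input/output contract:

1. **Disk candidates**: difference-of-Gaussian blob detection at the
   expected disk scale (known from the crop size, since the crop bounds the
   grid), subpixel-refined by a quadratic fit of the response peak and then
   by an intensity centroid over disk-level pixels. The centroid step
   matters: the DoG peak of a *border* disk is biased outward by the bright
   sheet edge, while the centroid over pixels above the sheet/disk Otsu
   threshold is not. It is only applied when the disk is resolved
   (estimated radius ≥ 5 px in the upscaled crop); below that, blur merges
   disks and the DoG peak is the better estimate.
2. **Tail candidates**: a morphological opening sized just above the cable
   half-width removes the cables from the thresholded object mask; the
   large elongated components of the residual are the cables, their
   centroids the tail candidates.
3. **Index assignment**: the four corner-most candidates (largest-area
   quadrilaterals on the convex hull; the top five are tried) anchor a
   projective map of the canonical grid plane; each of the four rotational
   hypotheses is refined by one least-squares pass over nearest-neighbor
   inliers and scored by inlier count; tails resolve ties among rotations
   (with no tails and a tied score, the assignment fails loudly with an
   ambiguity error rather than guessing); two more refinement passes and a
   one-to-one minimum-cost matching (Hungarian solver, gated at 0.45 of the
   projected pitch) produce the final electrode ↔ candidate assignment.
   Electrodes without a gated match are reported invisible. A quality gate
   rejects the frame if the refined fit explains fewer than 60 % of the
   electrodes — a silent misindexing is worse than a missing frame.

Cycle orientation deserves a note: seen from the front through a y-down
pixel frame, the canonical corner cycle always traverses with negative
signed area. Orientation is therefore enforced geometrically and never
scored — a reflected (back-side) assignment would score identically on the
symmetric lattice, but is physically impossible for an opaque grid.

Final keypoint coordinates come from the matched candidates themselves, not
from the fitted projective map (which is exact only for a flat sheet); the
map only provides the indexing and the tail keypoint positions.

## The evaluation protocol

`run_experiment()` replicates the relative-pose assessment used to validate
tracking accuracy against an optical tracker, with the simulator's known
geometry standing in for the tracker: the statistic, not the hardware, is
the content. The measurement grid places the flat grid at 30 positions — 6
depths (40–90 cm) x 5 lateral positions spanning a 32 cm working area — each
facing the left camera, the way the physical grid was oriented toward the
cameras at each position. At each position the scene is static and repeated
frames differ only by sensor noise, matching repeated recordings of a fixed
scene.

Per frame, the full pipeline runs on both views; a frame is *considered*
only if exactly one bounding box is detected in each view (stereo acceptance
rule), and a per-position median filter then rejects measurements whose
center (mean of valid triangulated points) lies more than 10 cm from the
component-wise median center — strictly more: a measurement exactly at the
threshold is kept. The filter is applied per position, since the grid is
static there; filtering globally across the session would mix depths and is
not what a static-scene outlier rule means. The false-positive rate is
rejected/considered, with 0/0 defined as 0 and flagged.

The closest central position (40 cm, centered) is the reference. For every
other position and electrode `i`,

    error_i = | ‖m_i(pos) − m_i(ref)‖ − ‖t_i(pos) − t_i(ref)‖ |

where `m` is the pipeline measurement (the reference is the mean over its
kept frames) and `t` the ground truth. Per position the report carries the
mean over frames of the frame-averaged (over electrodes) error, the standard
deviation of that frame average across frames, and — because it is not
obvious which spread a per-position summary should show — also the standard
deviation across electrodes of the per-electrode means. Per-electrode error
sums over all positions, normalized by the maximum electrode sum, give the
8x8 heatmap (maximum exactly 1 unless all errors are zero, which is
flagged).

The reference position's self-error is identically zero by construction and
is reported as such, marked `is_reference`.

### Problem sizes and defaults

The harness defaults are one scaled-down replication: 30 positions x 30
frames x 1 run (900 stereo frames), which `scripts/acceptance.R` and the
acceptance tests run end to end with the classical pipeline and default
rendering noise in a few minutes of CPU time. The corpus generator's
arithmetic is exercised at small `n_base` with a `dry_run` mode verifying
the full-scale 90,000 x 4 = 360,000 bookkeeping exactly. Monte-Carlo
properties (depth-monotone error growth, first-order depth-error
propagation Δz ≈ z²·σ_d/(f·b) within 25 %) run on direct triangulation with
synthetic pixel noise, which isolates the geometry from the image-processing
stages.

## Numerical choices and degenerate inputs

* Undistortion inverts the distortion polynomial by fixed-point iteration,
  20 iterations or 1e-10 convergence; round-trip accuracy is ~1e-3 px for
  |k1| ≤ 0.3.
* Triangulation uses the rectified closed form z = f·b/d; zero or negative
  disparity is a degenerate-geometry error, and in grid triangulation such
  indices are marked invalid rather than aborting the set (a full-set
  failure needs fewer than 4 mutually visible points).
* Downscale label bookkeeping multiplies coordinates by the *realized*
  per-axis ratio (26/80, not 0.33), so labels stay consistent with the
  floor-rounded image size; upscaling and crop bookkeeping use the pure
  multiplicative convention `x_full = x_up / factor + offset`.
* Detection score ties break by area then position; matching ties break by
  the solver's deterministic pivoting. Same-seed runs are bit-identical,
  including rendered images.
* All randomness flows from one master seed through fixed per-stage
  substreams; the RNG state of the caller is saved and restored around
  every seeded computation.

## Known limitations

* The classical pose path needs the disk lattice resolvable after x4
  upscaling; beyond ~70 cm with the default rig, visibility drops and
  errors grow to centimeter level — consistent with the operating-range
  limitation the method itself has — so accuracy guarantees are stated for
  the ≤ 60 cm band.
* The renderer's appearance model is deliberately minimal (see above);
  corpus images are meant for pipeline exercise and format compatibility,
  not as a substitute for a production training corpus.
* Deformation is evaluated by the geometry module's invariants; the
  experiment harness keeps the grid flat, matching the static, flat,
  facing-the-camera condition of the original evaluation protocol.
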