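---
title: "Quantifying microglial dynamics around cortical Aβ infusions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial dynamics around cortical Aβ infusions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gliadyn` quantifies how microglia respond to a focal bolus of fluorescently
labeled amyloid-beta infused into cortex, from two-photon ZT stacks (one
channel for the infusion, one for the microglial reporter), from filament
tracings of fixed-tissue microglia, and from single-plane histology images.
This vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the underlying procedure
was open to interpretation.

## The dynamics pipeline

### Registration and projection

Slow drift of the field of view is removed with a rigid-body model
(translation + in-plane rotation about the image center). Every frame is
registered **directly to the reference frame** (default: the first frame,
t = 0, the same frame that anchors the red/green displacement composites)
rather than successively to its predecessor: the contract is the same —
global drift removal — but direct registration cannot accumulate per-step
estimation error across 80 frames.

The estimate is computed on the **infusion channel's sum projection**,
because the bolus is the one structure guaranteed static over the session.
Translation comes from phase correlation: Hann-windowed frames, whitened
cross-power spectrum, and a Gaussian low-pass on that spectrum (cutoff
max(n)/8 cycles per image). The low pass matters: fluorescence frames carry
almost no signal in the upper spectrum, where whitening would otherwise let
shot noise dominate the correlation peak. The integer peak is refined to
sub-pixel precision by evaluating the correlation surface around it with a
matrix DFT at 50-fold upsampling. Rotation is a bounded coarse search
(±5° by default, 0.5° steps) over the phase-correlation peak height —
which is invariant to the unknown translation — followed by golden-section
refinement scored by the normalized cross-correlation of the fully aligned
frame over a 15%-margin central crop. NCC is used for refinement because the
peak-height objective is not smooth in the rotation angle, while NCC is.
One guard is deliberate: if the best rotation does not improve the NCC by at
least 10⁻⁴ over zero rotation, zero is kept. A centered, nearly circular
bolus constrains rotation very weakly, and without the guard the line search
wanders on noise and injects a spurious rotation into the green channel.

The per-frame transform is inverted and applied to every channel and z-plane
with bilinear interpolation (zero fill outside the frame), after which each
frame is collapsed to a sum-based XY projection. Projections are kept as
real values without clipping, so per-frame total intensity is conserved
exactly; all downstream metrics operate on these projections.

### Infusion mask

The infusion footprint is segmented from the red projection at the baseline
frame: Otsu threshold (foreground strictly above it), removal of 8-connected
components below `min_feature_area_px`, then dilation with a Euclidean disc.
Defaults — minimum area 64 px, dilation radius 3 px — are package choices:
the operations come from the established chain but their sizes are not fixed
by it, so both are arguments and both are recorded in the mask's provenance.
The returned Otsu threshold is the midpoint between the largest background
value and the smallest foreground value, so `image > threshold` reproduces
the variance-minimizing split exactly and the threshold is strictly between
the classes. For 16-bit data the histogram uses 256 equal-width bins
(`exact = TRUE` switches to per-value candidates).

### Coverage and distance series

Both read-outs share one detection rule. Baseline statistics (mean and
**population** SD — a fixed, deterministic definition whose difference from
the sample SD is negligible at these pixel counts) are computed on the green
projection at the baseline frame, by default **within the infusion mask**.
A pixel qualifies when its green intensity exceeds
`baseline mean + k·SD`, k = 1.5 by default. The multiplier rule "above 1.5
standard deviations" admits two readings — with or without the baseline
mean — and the mean-plus-k·SD form is the standard detection rule and the
only one well-defined for detectors with a non-zero offset; the bare `k·SD`
variant remains selectable (`include_mean = FALSE`), and the rule actually
used is recorded in the output attributes.

*Coverage* is the percentage of mask pixels qualifying per frame. *Distance*
erodes the mask (disc radius 2 px by default — small enough to keep the
eroded footprint close to the visible bolus, large enough that the zero level
set sits inside the dilated border), computes the exact Euclidean distance
transform of the eroded mask, converts to µm with the in-plane calibration,
and averages the map over qualifying pixels frame by frame. Pixels inside
the eroded mask contribute distance 0 by default (`exclude_inside` drops
them); whether the original analysis counted or excluded them is not
determinable, so the choice is explicit and logged. Frames with no
qualifying pixel yield `NA` rather than 0 — a zero would read as "contact"
and bias approach-speed fits. The approach speed is the negated OLS slope of
mean distance against time over the pre-contact window.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's recovery properties are demonstrated.

**What it emulates.** A static soft-edged bolus (plateau intensity with a
0.5 px Gaussian edge) in the red channel; in the green channel, microglia
placed on a ring around the bolus — soma disc, a fan of processes (the first
pointing straight at the bolus), and a bright growth-cone disc at each tip.
Cells advance toward the bolus at `process_speed_um_per_min`; when the
leading tip reaches the edge the cell halts and deposits a laterally
spreading band of bright material along the bolus rim, emulating
lamellipodial coverage, until the rim band saturates (the coverage plateau).
Advancing the whole cell, tips included, is what makes the all-pixel mean
distance fall at the configured speed — pure tip elongation would dilute the
slope with the static soma and shaft mass. Optional rigid drift (translation
and rotation per frame) is applied to the whole scene for registration
benchmarks. Default scale is 20 frames of 8 × 256 × 256 at 0.4 µm/pixel,
3 µm z-step, one frame per minute — the acquisition calibration at a
desk-testable matrix size; the full 11 × 1024 × 1024 × 80 scale is reachable
through `image_shape`.

**Noise model.** Poisson shot noise on the per-slice photon counts
(`photon_gain` intensity units per photon) plus optional additive Gaussian
read noise. The Gaussian term defaults to **zero**: two-photon acquisition
with photon-counting PMTs is shot-noise-limited, and read noise is the right
thing to add only when emulating analog detection. This default also keeps
the k·SD detection rule meaningful — a Gaussian noise floor passes a fixed
~7% of background pixels regardless of its scale, which is a property of the
detection rule itself, not of this implementation, and is worth knowing when
applying the rule to analog-detector data. At the default tip amplitude
(36 photons) the peak SNR is √36 = 6.

**Ground truth.** Truth is computed from the noiseless, drift-free
geometry: the bolus footprint is the half-maximum set of the noiseless red
projection; green support is every pixel with non-zero noiseless signal
(intensity profiles are truncated at 3σ, so support is compact);
true coverage and true mean distance are then computed exactly as the
pipeline defines them, but on these exact sets. The cell layout is drawn
from a separate `geometry_seed` stream, so the simulation `seed` changes
only the noise realization — two seeds share an identical noiseless scene.

**What passing does and does not show.** Closure and recovery tests
demonstrate that the implementation measures what it defines, at realistic
SNR, under the stated geometry. They do not show robustness to what the
generator omits: no optical PSF or depth attenuation, no photobleaching, no
microglia already inside the bolus at baseline, no deformable motion or
z-drift, and an idealized circular bolus. Real-data conclusions still
require the usual controls.

**Closure conditions.** The noiseless-closure and recovery experiments
segment with `dilation_radius_px = 0`, so the pipeline's footprint and the
truth's half-maximum footprint coincide; the 3 px dilation default remains
the recommendation for real data, where it absorbs the dim diffusion
gradient at the bolus border. Recovery experiments use Z = 4 slices —
after sum projection the green geometry is 2D by construction, so additional
slices only rescale the photon budget.

## Morphometry

Tracings are rooted trees with SWC semantics (ids, 3D coordinates in µm,
parent pointers, one root = soma). Total process length is the sum of
parent-child Euclidean edge lengths. A **branch point** is any non-root node
with ≥ 2 children; the root counts only with ≥ 3, since its first two
children can be the two ends of one process passing through the soma. The
tracing software's internal definition is not published, so this one is
stated and tested.

For population heatmaps every cell is translated to put its soma at the
origin and rotated so the soma→infusion-center direction maps onto +x — the
"central axis" of a cell is taken as this axis (the alternative,
soma→process-centroid, is noted but not implemented as the default since the
infusion direction is the experimentally meaningful one). Edges are
rasterized with supercover traversal (every cell the segment passes through,
so thin diagonal processes leave no gaps) into a grid with an odd number of
bins per side, putting one bin center exactly at the origin. Each tracing
increments a cell at most once: counts are numbers of overlapping microglia.
Quadrant coverage is the share of occupied cells per quadrant of the
oriented frame; cells whose center lies exactly on an axis are split
0.5/0.5 (0.25 each at the origin), so symmetric fixtures land on exact
values. With the odd-sized grid, axis-aligned processes land in the center
row/column and the tie rule makes a symmetric cross score exactly 25% per
quadrant.

## Staining metrics

All histology scores are threshold-based and deliberately explicit: the
original analyses set thresholds interactively, so here the threshold is a
required argument (or an Otsu flag) and is always recorded. Area fraction is
pixels strictly above threshold over region area. Puncta coverage places
four 200 µm × 200 µm ROIs deterministically at the compass positions
abutting the bounding box of the infusion edge — manual ROI placement is not
reproducible, deterministic placement is — and averages the per-ROI
fractions; an ROI that would leave the image is shifted inward (never
clipped) and flagged. Uptake is the fraction of labeled cells overlapping
the signal mask by at least `min_overlap_px` (default 1). Plaque surface
coverage floors both stacks at 500 intensity units (the standard background
cut for these acquisitions), takes the plaque surface as foreground voxels
with a background 6-neighbor, and counts a surface voxel covered when
microglia foreground lies within a Chebyshev radius (default 1 voxel). This
voxel-adjacency definition is declared, not claimed equivalent to
mesh-based surface-contact tools.

## Numerical conventions and edge cases

* Indices are 0-based in user-facing coordinates; y grows downward, x
  rightward; distances are µm via the sidecar calibration, never assumed.
* Otsu ties break toward the smaller threshold; constant images are errors,
  not silent thresholds.
* The Euclidean distance transform is exact (verified against an all-pairs
  brute force to < 10⁻⁹ px); connected components are 8-connected in 2D and
  26-connected in 3D.
* Volume estimates satisfy `total = voxels × voxel volume` identically; the
  voxel volume is a user-supplied calibration and is never derived from
  pixel sizes internally, because printed calibrations and printed voxel
  volumes in the field do not always agree and silently picking one would
  hide the discrepancy.
* Masks emptied by cleanup or erosion raise typed errors
  (`allow_empty = TRUE` opts out for cleanup); degenerate inputs (constant
  frames, somata coincident with the infusion center) are errors or explicit
  skips, never zeros.
* Every generator is deterministic given (config, seed) and restores the
  caller's RNG state.

## Verification scale

The shipped verification (test suite and `scripts/acceptance.R`) runs at:
200 random images for the Otsu oracle, 200 random masks (≤ 32 × 32) for the
distance-transform oracle, 20 noisy textured frames (256², SNR 5) for rigid
recovery, 20 seeded movies (256² × 20 frames, speeds 0.5–3 µm/min) for
approach-speed and plateau recovery, and 100 random trees/segments for the
morphometry oracles. These sizes were chosen to exercise the estimators well
inside a desk-scale run; all are plain parameters in the scripts.

## Known limitations

* Rigid-body drift only: no affine or deformable registration, no z-drift
  correction; rotation is estimated on projections, not plane by plane.
* Rotation is weakly identified when the field of view is dominated by a
  centered, circular structure; the zero-rotation guard then keeps the
  estimate conservative rather than accurate.
* The coverage/distance detection rule passes a fixed fraction of any
  Gaussian-distributed background; with analog detectors a higher `k` or a
  whole-frame baseline may be preferable.
* Filament tracings are inputs (SWC); the package does not trace cells from
  images and does not compute Sholl profiles.
* ROI placement for puncta coverage is a stated convention, not a
  reconstruction of any particular analyst's choices.
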