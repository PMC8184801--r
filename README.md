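# gliadyn

Quantification of microglial dynamics around focal amyloid-beta (Aβ)
infusions in cortex.

When a fluorescently labeled Aβ bolus is injected into cortex of a mouse with
a green microglial reporter (e.g. Cx3cr1-GFP), two-photon time-lapse imaging
shows microglial processes extending toward the bolus, reaching its edge and
spreading along it to encapsulate the material. `gliadyn` implements the
image-quantification pipeline for this experiment, for imaging groups and
analysts who need the read-outs to be scripted and reproducible rather than
assembled interactively in ImageJ/MATLAB/Imaris:

* **Preprocessing** — rigid-body drift correction of ZT stacks (phase
  correlation for translation, bounded search with normalized
  cross-correlation refinement for rotation, every frame registered directly
  to the reference), and sum-based XY projections.
* **Infusion segmentation** — Otsu threshold of the red (infusion) channel,
  removal of small components, disc dilation to smooth the border; 3D variant
  with voxel-count volume estimation (`voxels × voxel volume`).
* **Dynamics read-outs** — the two headline time series:
  * *percent coverage*: share of infusion-mask pixels whose green intensity
    exceeds `baseline mean + k·SD` (default `k = 1.5`, baseline = frame 0
    within the mask);
  * *mean distance*: the mask is eroded, its exact Euclidean distance
    transform computed, and every green pixel above the same threshold is
    assigned its distance to the infusion edge (reported in µm via the
    pixel calibration).
* **Morphometry** — SWC filament tracings: total process length and
  branch-point counts, rotation of each cell so its soma→infusion axis faces
  +x, supercover rasterization into an orientation heatmap, and per-quadrant
  process coverage.
* **Histology scores** — stain area fractions, mean puncta coverage in four
  200 µm × 200 µm ROIs abutting the infusion edge, fraction of labeled cells
  containing Aβ signal, and plaque surface-contact coverage in 3D.
* **Synthetic data** — a generator producing two-photon-like movies (static
  bolus, cells approaching at a set speed, Poisson shot noise, optional rigid
  drift), 3D volume stacks with analytic sphere volumes, filament sets and
  staining images — all with ground truth, so the whole pipeline is testable
  without any raw microscopy.

## Worked example

Simulate a movie at the default acquisition calibration (0.4 µm/pixel,
one stack per minute) with cells approaching at 1.5 µm/min, then run the full
dynamics pipeline:

```r
library(gliadyn)

cfg  <- simulation_config(process_speed_um_per_min = 1.5, seed = 7,
                          image_shape = c(T = 20L, Z = 4L, Y = 256L, X = 256L))
sim  <- generate_timelapse(cfg)
proj <- sum_projection(sim$stack)

mask <- segment_infusion(projection_frame(proj, 1, "infusion"))
mask
#> InfusionMask: 3507 foreground px | threshold 119.5, min area 64 px, dilation 3 px

base <- baseline_statistics(projection_frame(proj, 1, "microglia"), mask)
cov  <- coverage_series(proj, mask, baseline = base)
dmap <- eroded_distance_map(mask, erosion_radius_px = 2,
                            pixel_size_um = cfg$pixel_size_um)
dist <- mean_distance_series(proj, dmap, baseline = base)

head(data.frame(t_min = cov$t_min, coverage_pct = round(cov$coverage_pct, 1),
                mean_distance_um = round(dist$mean_distance_um, 2)), 4)
#>   t_min coverage_pct mean_distance_um
#> 1     0            0            21.54
#> 2     1            0            20.04
#> 3     2            0            18.54
#> 4     3            0            17.05

fit <- fit_approach_speed(dist, seq_len(sim$truth$first_contact_frame - 1))
round(fit$speed_um_per_min, 2)
#> [1] 1.49
```

The mean distance falls by ~1.5 µm per one-minute frame (the configured
approach speed; the least-squares fit over the pre-contact window recovers
1.49 µm/min), and after the processes reach the bolus the coverage rises to a
plateau (39.5% here — the lamellipodial band lining the bolus rim).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/exec/gliadyn.R simulate timelapse --seed 7 --out run/
Rscript inst/exec/gliadyn.R mask run/timelapse.tif run/mask.tif
Rscript inst/exec/gliadyn.R coverage run/timelapse.tif run/mask.tif --out run/coverage.csv
```

Identical inputs and seeds give byte-identical outputs.

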