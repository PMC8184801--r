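Package: gliadyn
Title: Quantification of Microglial Dynamics Around Cortical Amyloid-Beta Infusions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Image-quantification pipeline for two-photon time-lapse studies of
    the microglial response to focal amyloid-beta infusions in cortex. Provides
    rigid-body drift correction and sum projections of ZT stacks, Otsu-based
    segmentation of the infusion site with morphological cleanup, percent
    coverage of the infusion site by microglial processes over time, mean
    microglia-to-infusion distance series via Euclidean distance transforms,
    voxel-count infusion volume estimates, filament (SWC) morphometry with
    infusion-oriented heatmaps and quadrant coverage, and threshold-based
    histology scores (area fractions, puncta coverage in fixed ROIs,
    amyloid-uptake fractions, plaque surface-contact coverage). A synthetic-data
    generator produces time-lapse movies, volume stacks, filament sets and
    staining images with known ground truth so every stage is testable without
    raw microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
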