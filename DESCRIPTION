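Package: photospike
Title: Spike-Train, Photopharmacology and Place-Preference Analysis for
    Light-Controlled Nicotinic Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for experiments that photo-control
    nicotinic acetylcholine receptors on ventral tegmental area dopamine
    neurons. Implements inter-spike-interval burst detection (80 ms onset /
    160 ms closure), percent spikes-within-bursts, overlapping
    sliding-window rate series, event-aligned rasters and peri-stimulus
    time histograms, per-wavelength epoch firing frequencies and the
    photoswitching index with control-derived responder thresholds and
    type 1 / type 2 classification, photo-inhibition indices for
    agonist-evoked currents, nicotine i.v. response magnitudes with
    light-condition normalization, conditioned-place-preference occupancy
    and preference scores with pretest-balanced group assignment, and a
    normality-gated statistical decision tree with Holm-Bonferroni
    correction. A synthetic-data generator (bistable photoswitch state
    kinetics, light-modulated gamma-renewal bursting point process,
    nicotine transients, occupancy-conditioned arena trajectories) makes
    every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
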