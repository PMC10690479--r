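# punctatrack

Quantification toolkit for fluorescence-microscopy studies of motor-driven
membrane transport — the kind of experiment in which a clathrin adaptor
(e.g. AP1) marks endosomal puncta whose number, brightness, dispersion and
motility change when a trafficking factor is perturbed, and in which
candidate machinery is identified by a quantitative pull-down screen.

The package provides, as composable R functions:

- **Segmentation** — nuclei by a classical chain (median filter,
  rolling-ball background subtraction, a threshold controlled by a
  probability of false alarm, watershed, 8-connected components); cell
  territories by Euclidean-distance-transform assignment of each
  foreground pixel to its closest nucleus; puncta by
  Laplacian-of-Gaussian filtering or raw-intensity thresholding with a
  minimum-area filter.
- **Puncta statistics** — per-cell counts and mean total intensities; the
  signal *spread* statistic `S = Σᵢ wᵢ ‖pᵢ − c‖²`, where `wᵢ` is the pixel
  intensity and `c` the intensity-weighted centroid (reported raw, a.u.·px²,
  and normalized by total intensity, px²); object-based colocalization
  (overlapping puncta as a percentage of channel-1 puncta); fixed-area
  (300 µm²) zone quantification for embryo images.
- **Tracking and motility** — threshold-free spot detection by 2D Gaussian
  fitting with a false-alarm-calibrated acceptance, greedy
  minimal-displacement linking, discarding of tracks under 10 time points,
  per-track MSD over all point pairs and the pair-count-weighted mean MSD
  (`MSD(τ) = 4Dτ` for diffusion, `v²τ²` for directed motion), live
  object-based colocalization (a channel-1 track counts as co-localised at
  a timepoint when a channel-2 track spot lies within 300 nm; movie value =
  mean over the first 50 timepoints), and apical/basal run classification
  (% of trajectory time per motion class, run velocities and lengths).
- **Enrichment screen** — protein-level filtering (≥ 2 peptides, ≥ 3
  quantification events in a group), per-sample median normalization, log2
  transform with down-shifted normal imputation, the S0-moderated Welch
  statistic `t = (m₁ − m₂) / (√(s₁²/n₁ + s₂²/n₂) + S0)` with S0 = 0.1,
  permutation-based FDR q-values, and enrichment calls at
  log2 fold change > log2(10) = 3.322 and q < 0.05.
- **Synthetic data** — seeded generators for fixed-cell scenes, two-channel
  bead movies, trajectories (stationary / diffusive / directed /
  run-and-pause) rendered into movies, and spiked proteomics matrices, each
  emitting exact ground truth so every stage is testable without external
  data.

## Worked example

Simulate a two-channel movie of immobile beads, track both channels, and
measure live colocalization — the standard control for the 300 nm rule:

```r
library(punctatrack)

bead <- render_bead_movie(10, 60, scene_spec(image_shape = c(128, 128), seed = 1))
tracks <- lapply(1:2, function(ch) {
  spots <- detect_spots_movie(bead$scene, channel = ch)
  filter_tracks(link_tracks(spots, max_disp = 5), min_points = 10)
})
colocalize_live(tracks[[1]], tracks[[2]], dist_nm = 300, n_frames = 50)$percent
#> [1] 100
```

Identical spots in both channels must co-localise fully; the value printed
is the percentage of channel-1 tracks with a channel-2 spot within 300 nm,
averaged over the first 50 timepoints.

Motility analysis on simulated diffusing cargo:

```r
tr  <- simulate_trajectories(motion_spec("diffusive", n_particles = 500,
                                         n_frames = 100, D = 1e4, seed = 7))
fit <- fit_diffusion(msd_analysis(tr, frame_interval_s = 0.057)$mean)
fit$D
#> [1] 9963.401
```

The slope of the weighted mean MSD over the first ten delays recovers the
simulated diffusion coefficient (10⁴ nm²/s) to about 0.4% here.

An enrichment screen on a synthetic pull-down with 25 spiked interactors:

```r
sim <- simulate_proteomics_matrix(proteomics_sim_spec(
  n_proteins = 1000, n_spiked = 25, spike_log2_effect = 5,
  rep_log2_sd = 0.5, peptides_range = c(2, 20), seed = 2001))
tab <- enrichment_screen(sim$matrix, seed = 2001)
sum(tab$enriched)
#> [1] 25
all(tab$protein[tab$enriched] %in% rownames(sim$matrix$intensities)[sim$truth])
#> [1] TRUE
```

All 25 truly spiked proteins (32-fold enrichment) are called, with no
false positives, at the 10-fold / q < 0.05 criterion.

Whole pipelines can be described in YAML and run with
`run_pipeline(read_pipeline_config("config.yaml"))` or the thin wrapper in
`inst/scripts/pipeline.R`; every run writes a `provenance.json` with the
full configuration and seed.

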