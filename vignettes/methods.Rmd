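---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

punctatrack quantifies fluorescence experiments on motor-driven membrane
transport at four levels: fixed-cell images (segmentation and puncta
statistics), live movies (tracking, MSD, colocalization), bidirectional
transport (run classification), and interaction proteomics (enrichment
screen). This vignette records the models behind each stage, the
parameters that matter, and the design decisions taken where the
methodology left genuine choices.

## Coordinate and unit conventions

Images are matrices with y = row, x = column, origin at the top-left;
pixel centers sit at integer coordinates and subpixel positions are real
numbers on that grid. All physical conversions go through a single pixel
size (default 110 nm/px) and frame interval (default 0.057 s, a 17.5 Hz
streaming acquisition); both are configurable everywhere. Trajectory
simulations work directly in nm.

## Segmentation

Nuclei are segmented by a classical chain: median filter (radius 2 px),
rolling-ball background subtraction, a threshold controlled by a
probability of false alarm (PFA), optional distance-transform watershed to
split touching nuclei, and 8-connected component extraction with contiguous
relabeling.

The PFA threshold assumes an approximately Gaussian background. Its
center and scale are estimated robustly — median and MAD × 1.4826 — so
bright objects do not inflate the estimate, and the threshold is
`median + z(1 − pfa) · sigma`. The same machinery calibrates spot
acceptance in tracking. The realized false-alarm rate matches the nominal
one to within binomial error for pfa between 1e-2 and 1e-4 (tested on
4 × 10⁶-pixel noise images); a constant image has no defined threshold and
is rejected.

The rolling-ball step is implemented as grayscale morphological background
subtraction with a flat disc structuring element (radius 50 px by
default). A non-flat ball element changes the background estimate only
marginally at these radii and has no efficient implementation in the
installed stack; the flat-disc opening is the standard morphological
reading of the filter.

Cell territories: each foreground pixel is assigned to the nucleus whose
pixel set is closest in Euclidean distance (per-nucleus distance
transforms; pixels inside a nucleus are at distance 0). Ties break toward
the lowest label, making the partition deterministic; the assignment is
tested against an exhaustive nearest-nucleus-pixel search on 64 × 64
instances. The foreground itself is the smoothed (sigma 2 px) max-projection
over channels thresholded at a quantile (default 0.5) of its own intensity
distribution; the comparison is inclusive (≥) so the mask tends to the full
image as the quantile tends to 0, and adding a constant to the image leaves
the mask unchanged. Regions touching the image border are discarded as
incomplete cells.

Puncta are connected components of a thresholded −LoG response (scale
`log_sigma`, default 2 px, matched to the spot radius) with a minimum area
of 5 px. Two threshold modes are provided because the appropriate choice
depends on acquisition: `absolute` (threshold in response units) and `mad`
(threshold in robust sigmas of the response). Punctum intensities are
measured above the image's median background, which together with the
mean-zero LoG kernel makes detection *and* intensity readout invariant to
constant offsets. A raw-intensity threshold path
(`segment_by_intensity_threshold`) covers particle counting on unadjusted
channels, with the same 5-px minimum-area rule.

## Puncta statistics

The spread statistic of a signal inside a mask is
`S = Σᵢ wᵢ ‖pᵢ − c‖²` with `c` the intensity-weighted centroid. Both the
raw value (a.u.·px², the default readout) and the normalized value
`S / Σ wᵢ` (px², invariant to intensity rescaling) are reported: the raw
sum is the direct dispersal readout for comparing conditions at matched
intensities, while the normalized value is a variance with exact closed
forms (a symmetric two-point mass at distance 2r has normalized spread
r²). The reference point is the signal's own centroid, not a nuclear
landmark — with perinuclear signal the two nearly coincide, and the
centroid needs no extra segmentation.

Object-based fixed-cell colocalization counts a channel-1 punctum as
overlapping when its pixel set intersects any channel-2 punctum, and
reports the per-cell percentage of channel-1 puncta. The measure is
deliberately asymmetric (channel 1 is the reference); cells with no
channel-1 puncta yield a missing value rather than 0%.

Zone quantification uses half-open rectangles (`[x0, x1) × [y0, y1)`), so
a punctum centroid on a shared boundary is counted exactly once. Every
rectangle must measure 300 µm² within 1 px², the fixed-region convention
for comparing apical, upper-basal, lower-basal and yolk zones across
embryos.

## Spot detection and tracking

Detection is threshold-free in the sense that the user supplies no
intensity cutoff: candidates are local maxima of a matched-filter response
(mean-zero Gaussian blob kernel, unit L2 norm), and the acceptance level is
the `1 − pfa` quantile of a robust Gaussian fit to the candidate responses
themselves. Self-calibrating on the statistic actually thresholded keeps
the realized false-alarm rate near nominal (within a factor of ~2 at
pfa = 0.01, the regime where the Gaussian tail approximation of the
local-maxima distribution is accurate; tested over 100 noise frames).
Accepted candidates are refined by least-squares symmetric 2D Gaussian
fits (Levenberg–Marquardt; window 7 px, ≥ 5 px required), giving subpixel
position (±0.05 px at high SNR), sigma, amplitude, and the integrated
intensity `2π·A·σ²`. Non-convergent fits are dropped and counted.

Linking is greedy minimal-displacement frame-to-frame assignment:
candidate links sorted by distance, accepted shortest-first, links beyond
`max_disp` (default 5 px) forbidden, and optional gap closing across
`memory` missed frames (default 0). This is deterministic and matches the
behaviour of classical nearest-neighbour particle-tracking codes at the
moderate densities the package targets. Tracks with fewer than 10 time
points are discarded before MSD analysis — short tracks make MSD estimates
unreliable — and an optional polygonal ROI removes tracks whose mean
position lies outside cells.

## MSD analysis

Per track, `MSD(τ = k·Δt)` averages `‖p(i+k) − p(i)‖²` over all ordered
pairs k frames apart; the pair count is the weight. Delays are limited to
the first 25% of the track duration by default to bound estimator
variance. The across-track mean weights each track's MSD by its pair count
at that delay; delays covered by no track are omitted. Closed forms used
as tests: stationary → 0; ballistic → `v²τ²` exactly; a diffusive ensemble
(500 tracks × 100 frames at D = 10⁴ nm²/s) recovers the slope `4D` within
10% from the first ten delays. `fit_diffusion` performs that
weighted zero-intercept fit.

## Live colocalization

At each timepoint, a channel-1 track *present at that timepoint* counts as
co-localised when any channel-2 track-member spot lies within 300 nm
(approximately the microscope resolution); the movie value averages the
per-timepoint percentages over the first 50 timepoints to limit the
contribution of transient encounters. The denominator counts only tracks
present at the timepoint — the natural reading of a per-timepoint
percentage; with the 10-point track filter the alternative (all tracks in
the movie) differs only when tracks end inside the averaging window. The
two-channel immobile-bead control, run end-to-end through detection,
linking and filtering, must and does report exactly 100%.

## Run classification

Per-frame axial velocity (projection of the displacement on the apical
axis, default −y, divided by Δt) is smoothed with a centered moving
average (3 frames). Frames with axial velocity ≥ v_min are apical, ≤
−v_min basal, the rest stationary; contiguous frames merge into segments,
and moving segments whose net axial excursion is below `min_run_length`
are reclassified as stationary — so the inclusion threshold can only lower
the moving-time percentages. Defaults v_min = 100 nm/s and
min_run_length = 500 nm sit between typical pause jitter (< 50 nm/s
apparent) and motor-driven runs (hundreds of nm/s over microns); both are
exposed and echoed in the output metadata, as such thresholds are
acquisition-dependent and inherited tracking scripts rarely publish them.
Class percentages sum to 100 by construction. On simulated run-and-pause
trajectories (60 particles × 400 frames, exponential dwells of 3/1/2 s)
the classifier recovers the ground-truth apical-time percentage within 5
points; the residual bias comes from state switches landing inside a
smoothing window.

## Enrichment screen

The screen starts from a proteins × samples intensity matrix (iBAQ-like,
missing values allowed). Stages, in order:

1. **Filter** — keep proteins with ≥ 2 peptides and ≥ 3 quantification
   events in at least one group; drop reverse-database and contaminant
   flags.
2. **Normalize** — divide each sample by the median over complete rows
   (proteins quantified in every sample), making the complete-row medians
   equal; using a fixed reference set keeps the operation invariant to
   per-sample scaling.
3. **Log2 + impute** — missing values drawn per sample from
   `Normal(mean − 1.8·sd, (0.3·sd)²)` of the observed log2 intensities.
   The downshift/width pair (1.8, 0.3) is the de-facto standard for
   missing-not-at-random dropout in label-free proteomics; both are
   exposed, and imputation is seed-reproducible.
4. **Test** — S0-moderated Welch statistic with S0 = 0.1, damping
   tiny-variance small-effect proteins; log2 fold change is
   median(group 1) − median(group 2) (a mean mode is available for
   sensitivity checks).
5. **Permutation FDR** — for each threshold on |t|,
   `FDR = mean permuted count / observed count` (capped at 1); a protein's
   q is the minimum FDR over thresholds at or below its own |t|, which is
   monotone non-increasing in |t| by construction. With 3 vs 3 samples only
   10 distinct group *partitions* exist, so all distinct partitions are
   enumerated (excluding the observed one) and used with equal weight
   rather than sampling 250 labelings with replacement: a labeling and its
   mirror produce identical |t|, and keeping the observed partition in the
   null would floor the attainable FDR at ~1/n_perm. The number of
   permutations actually used is recorded on the result.
6. **Call** — enriched ⇔ log2fc > log2(10) = 3.322 (strictly) and
   q < 0.05 (strictly).

On synthetic 3 vs 3 screens (1000 proteins, replicate sd 0.5 log2 units,
20 seeds) the pipeline shows type-I control (null fraction of q < 0.05 at
the per-mille level) and full sensitivity at 32-fold spikes with realized
false-discovery proportion 0.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, pure functions of their specs:

- **Scenes** — disk nuclei plus diffraction-limited puncta rendered as
  isotropic 2D Gaussians *integrated over each pixel* (so summed pixel
  values equal nominal integrated photons), constant background, Poisson
  or Gaussian noise.
- **Bead movies** — identical subpixel positions in both channels, every
  frame; the ground truth for the 100% colocalization control. Beads are
  placed with a minimum separation of 6 PSF sigmas: the control's premise
  is individually resolvable beads, and spots overlapping within the PSF
  scale bias single-emitter fits differently in each channel, which would
  test fit interference rather than the colocalization procedure.
- **Trajectories** — exact diffusive steps (variance 2DΔt per axis),
  exact directed steps (vΔt), and a three-state run-and-pause semi-Markov
  process (exponential dwells; runs relax to pause; pauses exit apically
  with probability p) with reflecting boundaries for renderability.
- **Proteomics** — log-normal protein intensities, replicate noise,
  spiked group-2 effects, and logistic intensity-dependent dropout.

They deliberately omit optical aberrations, depth-dependent background,
nucleus shape irregularity, particle blinking and fusion/fission events,
camera gain beyond Poisson/Gaussian, and correlated (batch) proteomics
noise. Passing tests therefore demonstrate correctness of the
computations and calibration under the stated models — not robustness to
every real-data pathology; the PFA-based thresholds and robust background
fits are the package's main hedge against the latter.

## Numerical choices and degenerate inputs

- 8-connectivity everywhere for components; EBImage's 4-connected
  labeling is augmented by a deterministic union-find merge of diagonal
  neighbours.
- Robust background fits use median/MAD; zero MAD (constant input) is an
  error for thresholds and a fall-back to "any positive blob response"
  for noise-free spot detection.
- EDT ties break toward the lowest nucleus label; rectangle membership is
  half-open; linking processes candidate links in sorted order — all
  outputs are deterministic given the config and seed.
- Empty inputs return typed empty results (empty puncta sets, empty track
  sets); undefined ratios (no reference puncta/tracks) are NA, never 0.
- Test problem sizes were chosen for tight statistical power at
  interactive runtimes: 4 × 10⁶-pixel noise fields for threshold
  calibration, 500 × 100 trajectories for MSD closed forms, 20-seed
  batches of 1000-protein screens for error control.

## Known limitations

- The greedy linker is not a global (Hungarian/JV) optimum and will make
  occasional swaps at high particle density; at the densities tested
  (≤ 10 particles per 128² field) link recovery exceeds 90%.
- The LoG detector reports merged puncta as single objects when spots
  overlap within the kernel scale.
- `read_image_stack` relies on the caller for channel count and physical
  calibration; TIFF metadata is not parsed.
- Permutation q-values are granular at small sample sizes (9 informative
  partitions for 3 vs 3); this is a property of the design, not the
  implementation.
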