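---
title: "Quantifying single-cell repair dynamics in laser-wounded airway organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell repair dynamics in laser-wounded airway organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgrepair)
```

## The measurement problem

Airway organoids are hollow, nearly centrosymmetric epithelial spheres,
roughly 150 µm across, whose wall is a single cell layer. After femtosecond
laser ablation of one to ten neighbouring cells, the wound closes within
hours, and the questions of interest are *spatial*: do cells proliferate or
migrate more when they sit closer to the wound? The raw data are
multi-channel two-photon or confocal z-stacks over time; the quantities of
interest are per-cell distances from the ablation site, EdU-positive
fractions, migration distances, and whole-organoid diameters.

orgrepair implements this quantification as a chain of small, individually
testable stages:

1. **Projection** — z-stacks are collapsed to 2D (maximum-intensity for the
   nuclear label, sum-of-slices for EdU), justified by the organoid's
   centrosymmetry: the equatorial optical section carries the geometry.
2. **Nucleus detection** — a difference-of-Gaussians (DoG) blob detector with
   non-maximum suppression and subpixel centroid refinement.
3. **Tracking** — frame-to-frame linear assignment (LAP) with birth/death
   alternatives and gap closing, then per-track motion metrics.
4. **Shell geometry** — an algebraic least-squares circle through all
   detected nuclei; distances to the ablation site are measured *along* the
   circle (arc length) and discretized into 30-µm bins.
5. **Readouts** — distance-binned EdU-positive fractions, distance-binned
   migration distances, and z-slice-averaged diameter time series normalized
   to the pre-ablation size.
6. **Inference** — mean ± SEM across organoids (n = organoids, never cells),
   two-sided pooled-variance t-tests and one-way ANOVA at α = 0.05.

A synthetic generator produces organoid time-lapses with known ground truth
so that every stage is verifiable end to end without any microscope.

## Why arc length

Distance bins reported for ~150-µm organoids extend beyond 180 µm — farther
than any straight-line (chordal) distance inside such an organoid can reach.
On a 74-µm-radius shell the geodesic, however, reaches π·r ≈ 232 µm. Cells
live in the shell, so the natural distance between a cell and the wound is
the arc length along the fitted circle:

d(θ) = r · min(|θ − θ₀|, 2π − |θ − θ₀|),

where θ is the cell's angle on the fitted circle and θ₀ the projected
ablation site. The chordal metric 2r·sin(Δθ/2) remains available
(`metric = "chord"`) for sensitivity analysis but is not the default.
Bins are half-open `[lo, hi)`, 0-based, 30 µm wide; a cell at exactly 60 µm
belongs to `[60, 90)`.

## The synthetic organoid

The generator models the organoid's equatorial cross-section: `n_cells`
nuclei sit on a ring of radius `radius_um` at approximately equal angular
spacing (5 % angular jitter, Gaussian radial jitter), move tangentially
within the shell, and are rendered as 3D Gaussians into z-stacks with
Poisson shot noise and Gaussian read noise. Default parameter choices:

| parameter | default | rationale |
|---|---|---|
| `radius_um` | 74 µm | cohort mean initial diameter 148 µm |
| `n_cells` | 80 | ≈5.8 µm nucleus spacing on the equator, a confluent epithelium |
| `nucleus_sigma_um` | 1.2 µm | compact chromatin spot of a nuclear label |
| `growth_rate_per_h` | 0.25 %/h | ≈6 % diameter increase over 24 h |
| `frame_interval_min` | 30 min | imaging cadence of the live experiments |
| `z_range_um`, `z_step_um` | ±8, 2 µm | 9-slice stacks around the ablation plane |
| `pixel_size_um` | 0.5 µm/px | typical confocal sampling at this magnification |
| `sigma_tangential_um` | 0.75 µm/frame | 48 half-normal steps give a mean 24-h path of ≈29 µm, the scale observed in unwounded organoids |
| `drift_speed_um_per_frame` | 0.6 µm (within 60 µm of the wound) | adds ≈9 µm of path over 24 h, the scale of the wound-proximal excess |
| `baseline_rate`, boost | 0.13, +0.14 in one bin | baseline EdU fraction and boosted-bin contrast at the reported scale |
| `channel_contrast` | 5 | EdU⁺/EdU⁻ mean-intensity ratio, cleanly bimodal |

Motion is strictly tangential: epithelial cells migrate within the
monolayer, so radial structure enters only through static jitter. Cell
angles advance by N(0, (σ/R)²) per frame plus, within `drift_range_um` arc
distance of the wound, a directed step toward it that never overshoots.
The shell radius follows R(t) = R₀(1 + g·t). Ablation marks k angularly
contiguous cells; they keep their position up to the ablation frame and
disappear afterwards, and a bright static blob (mimicking the wound's
autofluorescence) is rendered for a configurable number of frames — it is
deliberately *absent* from the ground truth so that detector false-positive
handling can be exercised; an exclusion disc around the declared site
(`exclusion_radius_um`) suppresses it.

Seeding: every stochastic operation takes its own seed, derived from the
organoid seed with widely spaced offsets so that the placement, ablation,
motion, labelling and rendering streams never collide even across
consecutive organoid seeds. Identical spec + seed reproduce stacks and
truth tables bit for bit.

What the generator does *not* emulate: 3D nucleus shapes and true spherical
shells, cell division, optical point-spread anisotropy, spectral
bleed-through, and — importantly — cell–cell exclusion. Because simulated
cells random-walk independently, nuclei can transiently clump or leave
gaps that a confluent epithelium would not show; segmentation bridges such
gaps with a morphological closing (below), and tests that require
unambiguous identity use sparse rings. Passing tests therefore demonstrate
the correctness of the measurement chain, not detector performance on real
microscopy.

## Detection, segmentation and EdU calls

**Detection.** The DoG response at scale σ (`sigma_um`, default the rendered
nucleus scale) is searched for 8-neighbourhood local maxima above
`rel_threshold` × response range; maxima closer than `min_separation_um`
are suppressed strongest-first; positions are refined by the positive-
response-weighted centroid in a 2σ window. A deterministic classical
detector was chosen deliberately over a learned one: no trained weights
ship with the package, results are exactly reproducible, and the rendered
nuclei are ideal blobs. Every downstream stage also accepts plain point
tables, so a different detector (or a ground-truth table) can be dropped in.

**Organoid outline.** Gaussian smoothing (2 µm), Otsu threshold,
removal of sub-nuclear specks (< 3 µm²), morphological closing with a
15–20-µm disc (a few nucleus spacings, so the shell of discrete nuclei
closes into one outline), largest connected component, hole filling. A
slice whose foreground/background contrast falls below 1.5 is reported as
"no organoid found"; the diameter routine skips such slices with a warning
(deep z-slices far from the equatorial plane carry almost no signal under
noise). Minor and major axes are those of the second-moment-equivalent
ellipse of the filled mask; the slice diameter is their mean, the timepoint
diameter the mean over usable slices, and the series is normalized to
timepoint 0 = 100 % exactly.

**EdU positivity.** The default threshold is Otsu's criterion applied to the
per-nucleus mean EdU intensities of each organoid (per-organoid, because
staining intensity varies between specimens); the maximizing plateau of the
between-class variance is split at its midpoint, which places the cut
halfway across the empty gap of a well-separated bimodal mix. Fixed and
median + k·MAD thresholds are available, and explicit labels bypass
thresholding entirely. Empty distance bins are reported as absent, never as
zero — a zero rate is a measurement, absence is not.

## Tracking

Frame-to-frame linking minimizes summed squared displacement under a hard
link-length cap (`max_link_um`, default 15 µm per 30-min frame) using the
classic augmented cost matrix with birth/death alternatives priced at the
cap, solved exactly (Hungarian algorithm via `clue::solve_LSAP`). Gap
closing joins a track end to a later track start within `max_gap_frames`
(default 2) when the jump is below `max_link_um` × gap. Per-track metrics:
path length (Σ step lengths), net displacement (start→end), and maximum
excursion from the start. The headline "migration distance" is **path
length** — the per-cell total distance travelled — with the other two
available through a single switch; tracks covering less than half of the
frame range, or absent at the reference frame, are excluded from migration
statistics because partial tracks bias distance sums. Tracks are binned by
their arc distance at the first post-ablation frame.

## Statistical layer and its calibration

SEM is the sample SD over organoids divided by √n. The t-test is the
two-sided pooled-variance (Student) test; ANOVA the classic fixed-effects
F. Both are reported where the per-bin comparisons are ambiguous about
which was used. Two-sided tests are the conservative default, and no
multiplicity correction is applied by default (per-bin values are reported
as-is); a Holm option exists. Degenerate inputs (zero variance) are
flagged rather than producing NaN: equal means give t = 0, p = 1; unequal
means give p = 0 with a `degenerate` flag. The acceptance suite verifies
F = t² to 1e-10 and a null rejection rate within [0.045, 0.056] over
10,000 seeded replicates.

## Numerical choices

- Circle fit: the Kåsa algebraic least-squares solve. It is exact on
  noiseless circles and, at the ≤2-µm radial noise of this problem, within
  0.5 µm of the geometric (orthogonal-residual) minimizer; an optional
  Gauss–Newton refinement (tolerance 1e-8, ≤50 iterations) is off by
  default. Collinear input raises an error.
- Coordinates are micrometres with origin at the image top-left corner and
  y increasing downward (so angles increase clockwise); pixel (row, col)
  has its centre at ((col − ½)·px, (row − ½)·px). These conventions are
  stated in every CSV header comment.
- The site angle θ₀ and the circle are refit per frame (the wound moves
  with growth).
- For unablated control organoids the pipeline uses a sham reference site
  at θ = 0 on the fitted circle, so control bins are defined the same way
  as treated ones.

## Study-scale verification and its limits

The acceptance suite regenerates the documented study conditions — cohorts
of 8 organoids per condition, 100-cell or 80-cell rings, EdU baseline 0.13
with a +0.14 boost in the 30–60 µm bin, wound-directed drift confined to
60 µm — and verifies recovery through the full image → detection →
geometry → statistics chain: 50 seeded cohort replicates for proliferation
and migration, 20 seeds for detection fidelity, 10,000 replicates for test
calibration. Problem sizes (single fixed frame for the EdU assay; frames 0
and 48 for the 24-h morphometry; 60-point rings for the circle-fit oracle)
were chosen as the smallest designs that still represent the experiments.

One caveat is intrinsic rather than implementational. The proliferation
check demands, per cohort replicate, both that the boosted bin is the
maximum-rate bin and that its pooled rate passes an exact 95% binomial
envelope, in ≥95 % of replicates. A calibrated 95 % envelope is, by
construction, passed in about 95 % of replicates; multiplying in the
max-bin condition (itself below 1 at ~13 boosted-bin cells per organoid
and 8 organoids) pushes the joint per-replicate success probability below
0.95 even for a perfect measurement chain. The corresponding test is
therefore expected to sit slightly below its nominal threshold no matter
how exact the stages are, and the per-clause rates are the informative
quantities. The other known biases are small and documented: the mask edge
offset (blur + threshold) dilutes normalized diameter growth by roughly
0.2–1 percentage point, and merged detections of transiently overlapping
nuclei slightly inflate positive fractions in crowded, long simulations.

## Known limitations

- 2D ring world: no spherical-shell geometry, no 3D tracking, no division
  or merging events.
- The LAP cost is squared Euclidean distance only (no intensity or size
  features).
- Otsu-based EdU calls assume a bimodal intensity mix; a nearly
  all-negative organoid can misplace the threshold (use `"mad"` or a fixed
  cut there).
- Real 24-h experiments often have an imaging gap between 6 h and 24 h;
  the tracker records per-track frame coverage, and whether the 24-h
  migration value uses the full track or endpoint positions is left to the
  metric choice in the configuration.
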