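# orgrepair

Single-cell spatial quantification of epithelial repair in airway organoids
after targeted laser ablation.

Airway organoids are hollow, nearly centrosymmetric epithelial spheres
(~150 µm) whose wall is a single cell layer. After femtosecond-laser
ablation of 1–10 neighbouring cells, the wound closes within hours; the
analytical question is spatial: **do cells proliferate or migrate more the
closer they sit to the wound?** orgrepair turns multi-channel, multi-frame
z-stacks (or pre-detected point tables) into distance-resolved answers:

- z-projection (maximum-intensity or sum-of-slices) and
  difference-of-Gaussians **nucleus detection** with subpixel centroids;
- **LAP cell tracking** (optimal frame-to-frame linear assignment with
  birth/death alternatives and gap closing) and per-track motion metrics —
  path length, net displacement, maximum excursion;
- **shell geometry**: an algebraic (Kåsa) least-squares circle through all
  nuclei; each cell's distance from the ablation site is the *geodesic* arc
  length `d = r·min(|θ−θ₀|, 2π−|θ−θ₀|)` along that circle, discretized into
  half-open 30-µm bins (`[0,30)`, `[30,60)`, …);
- **readouts**: distance-binned EdU-positive fraction (relative
  proliferation rate), distance-binned mean migration distance, and
  z-slice-averaged organoid diameter normalized to the pre-ablation size;
- **inference**: mean ± SEM across organoids (n = organoids, not cells),
  two-sided pooled-variance Student's t-test and one-way ANOVA at α = 0.05;
- a **synthetic organoid generator** (ring of nuclei rendered into noisy
  3D stacks, with tangential motility, wound-directed drift,
  distance-dependent EdU labelling, and ground-truth tables) that makes the
  whole chain verifiable without a microscope.

It is aimed at microscopy groups doing organoid wound-healing assays who
want a reproducible, scriptable alternative to ad-hoc macro/Matlab chains.

## Worked example

Simulate one fixed-timepoint EdU specimen (5 cells ablated, labelling
probability 0.13 everywhere plus 0.14 extra in the 30–60 µm bin), then run
the full measurement chain:

```r
library(orgrepair)

spec  <- organoid_spec(seed = 42, n_frames = 1)   # 80 cells, r = 74 um
truth <- apply_ablation(make_organoid(spec), k = 5)
truth <- assign_edu_labels(truth, label_spec(0.13, c("1" = 0.14)))
stack <- render_stack(truth, frames = 0, scar_frames = 0)

mip <- project(stack, channel = 1, mode = "max", z_window = c(-6, 6))
edu <- project(stack, channel = 2, mode = "sum")
det <- measure_intensity(detect_nuclei(mip), list(ch1 = mip, ch2 = edu))

fit  <- fit_circle(det)
site <- ablation_site(truth$ablation$center_xy_um[1],
                      truth$ablation$center_xy_um[2], fit)
pr   <- proliferation_map(det, fit, site)
fit; pr; head(pr$per_bin, 3)
```

```
circle_fit: centre (97.48, 97.37) um, r = 73.86 um, rms = 1.39 um (n = 80)
proliferation_result: overall 17.5% (14/80), 8 bins
  bin_index lo_um hi_um n_total n_pos      rate
1         0     0    30      11     3 0.2727273
2         1    30    60      10     2 0.2000000
3         2    60    90      10     4 0.4000000
```

Reading this: all 80 nuclei were detected and fall on a circle of radius
73.9 µm (truth: 74 µm, residual 1.4 µm ≈ the radial jitter). 14 of 80 cells
(17.5 %) are EdU⁺; the per-bin table gives the positive fraction per 30-µm
arc-distance bin from the wound — with only ~10 cells per bin a single
organoid is noisy, which is why rates are aggregated as mean ± SEM across
cohorts of ≥8 organoids (`aggregate_condition()`) before testing
(`t_test_unpaired()`, `one_way_anova()`).

For time-lapse data the tracking layer works the same way:
`build_tracks()` on per-frame detections, then
`migration_map(tracks, fit, site, metric = "path_length")` for the
distance-binned migration readout, and `diameter_series(stack)` for
normalized growth curves.

A complete two-condition experiment (simulate → detect → track → geometry →
proliferation → migration → morphometry → stats → figures) runs from one
YAML configuration:

```r
run_pipeline(system.file("extdata", "example-config.yaml",
                         package = "orgrepair"), stage = "e2e")
```

or from a shell via the bundled wrapper
`inst/scripts/organoid-pipeline.R`. Every run writes its fully resolved
configuration next to its outputs; identical config + seed reproduce every
CSV byte for byte.

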