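# ujtmorph

Morphometrics of the epithelial **unjamming transition (UJT)**: when a
confluent, jammed (solid-like) epithelium becomes collectively migratory
(fluid-like), its cells elongate and its actomyosin machinery reorganizes.
In pseudostratified airway epithelium the basal stem cells at the
substrate interface remodel too — they enlarge, elongate, and accumulate
aligned stress fibers. `ujtmorph` is an R package for quantifying exactly
these changes from fluorescence z-stacks and phase-contrast time-lapses:

- **Slab projections** — maximum-intensity projections of apical, basal,
  and fiber-plane slabs of F-actin z-stacks, with explicit µm calibration.
- **Cell morphometry** — marker-controlled watershed segmentation of
  cortical-actin boundaries (h-minima markers, watershed lines), ridge
  quality control (tortuosity, length, intensity), area filtering, and
  ellipse-fit shape metrics. A cell's aspect ratio is AR = major/minor
  axis of the ellipse with the same normalized second central moments as
  the pixel region; densities are cells/mm².
- **Stress fibers** — iterative fragment tracing that keeps crossing
  fibers whole, fragment joining under gap/orientation constraints plus an
  intensity-continuity check, mean fiber length and total-length density
  (Σ length / searched area, µm⁻¹).
- **Alignment AUC** — structure-tensor orientation fields on a 3×3 µm
  grid (axial, double-angle representation), and the area between the
  pairwise alignment-versus-distance curve cos 2(θᵢ−θⱼ) of the observed
  field and that of the same orientations randomly repositioned: a single
  number for local-over-global fiber alignment.
- **Migration speed** — Farnebäck-style polynomial-expansion dense optical
  flow, 10 µm grid seeding, forward trajectory integration, and
  net-displacement speed in µm/h.
- **Statistics** — per-FOV/per-well aggregation, one-way ANOVA with
  Tukey–Kramer post-hoc comparisons, Pearson correlations.

Every stage is paired with a synthetic-microscopy generator (Voronoi cell
fields with controllable anisotropy, PSF-convolved fiber fields with
controllable orientation correlation, analytically advected time-lapses)
that exports exact ground truth, so the whole chain is covered by
parameter-recovery tests.

## Worked example

Generate a synthetic elongated epithelium, segment it, and recover the
imposed shape statistics; then do the same for fibers and migration:

```r
library(ujtmorph)

cf <- generate_cell_field(cell_field_spec(n_cells = 100, target_ar = 2,
                                          rng_seed = 7))
seg <- segment_cells(projection(cf$image, "apical", 1))
cell_morphology(seg)
#> CellMetrics: 100 cells, 498.9 cells/mm2, mean area 1927.1 um2, mean AR 2.08
mean(cf$truth$cells$aspect_ratio)   # generator truth: 2.066

ff <- generate_fiber_field(fiber_field_spec(rng_seed = 11))  # 200 fibers
fp <- projection(ff$image, "fiber", ff$spec$pixel_size_um)
join_fragments(trace_fragments(fp), fp)
#> FiberSet: 185 fibers, mean length 3.03 um, density 0.0140 um^-1 over 40000 um2
# truth: mean 3.00 um, density 0.0150 um^-1

tl <- generate_timelapse(flow_spec("translation", speed_um_per_h = 4))
integrate_trajectories(compute_flow(tl), 10)
#> TrajectorySet: 144 seeds (144 retained), 1.50 h, mean speed 3.970 um/h
```

The recovered cell count is exact, mean AR is within 1% of truth, fiber
length metrics are within 10% (fibers closer than the optical resolution
fuse, biasing density slightly low), and a 4 µm/h drift is recovered to
better than 1%.

Real data enter through `read_stack()` + `max_project()` (multi-page
TIFF z-stacks) and the same segmentation/tracing calls; a thin
command-line front end over these functions is included at
`inst/scripts/ujt-pipeline.R` (subcommands `project`, `segment-cells`,
`segment-fibers`, `fiber-align`, `track`).

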