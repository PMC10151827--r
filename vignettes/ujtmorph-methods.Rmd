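---
title: "Quantifying basal-cell and stress-fiber remodeling during epithelial unjamming"
author: "ujtmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying basal-cell and stress-fiber remodeling during epithelial unjamming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ujtmorph)
```

## The measurement problem

A confluent pseudostratified airway epithelium can switch from a solid-like,
non-migratory (jammed) state to a fluid-like, collectively migratory
(unjammed) state — the unjamming transition (UJT). The classical readouts of
this transition are apical cell elongation and collective migration speed.
`ujtmorph` implements the full image-analysis chain needed to add the basal
side of the story: the shapes of basal stem cells at the substrate interface
and the length and spatial alignment of their actin stress fibers, plus the
migration readout itself. Each stage is paired with a synthetic-image
generator that knows its own ground truth, so every estimator in the chain
has a parameter-recovery test.

The pipeline has five measurement stages:

1. **Slab projections** of F-actin z-stacks (apical boundaries, basal
   boundaries, basal fiber plane).
2. **Cell segmentation** by marker-controlled watershed with ridge-level
   quality control, and ellipse-fit morphometry (area, aspect ratio,
   density).
3. **Stress-fiber tracing** (fragment extraction, fragment joining) and
   length statistics.
4. **Orientation fields and Alignment AUC**, a statistic for
   local-over-global fiber alignment.
5. **Migration speed** from dense optical flow with grid-seeded forward
   trajectory integration.

A sixth module aggregates per-field metrics and reproduces the study-style
statistics (one-way ANOVA with Tukey–Kramer post-hoc comparisons, Pearson
correlations).

## Image conventions

Images are numeric matrices `[row = y, col = x]` with intensities on [0, 1];
16-bit grayscale TIFF is the interchange format. Physical calibration is
carried explicitly (`pixel_size_um`, `z_step_um`, frame interval in
minutes). Pixel `(r, c)` has its centre at `((c - 0.5), (r - 0.5)) *
pixel_size_um`. All orientations of fibers and cells are *axial* (defined
modulo 180°) and every average or comparison of orientations happens in
double-angle space: an orientation θ is the unit vector
(cos 2θ, sin 2θ), so θ and θ + 180° coincide and the alignment of two
orientations is cos 2(θᵢ − θⱼ) — +1 parallel, −1 perpendicular.

## Slab projections

Stacks are read with ascending z from substrate to apical surface. Depth is
measured downward from the top (apical-most) slice, and a slab `[z_lo,
z_hi)` selects every slice whose depth lies in the half-open window; the
projection takes per-pixel maxima over the slab. Interactive per-field
plane picking is deliberately replaced by fixed, configurable depth
windows; the defaults are

| plane  | window (µm below apical reference) | rationale |
|--------|------------------------------------|-----------|
| apical | [0, 4)                             | boundaries visible in the top few µm |
| basal  | [13, 16)                           | basal boundaries sit ≈13 µm below the apical surface |
| fiber  | [15.2, 16.7)                       | stress fibers ≈2.2 µm below the basal boundary plane |

The fiber offset is measured from the *top* of the basal slab, matching the
description of the fiber plane as ≈2.2 µm below the focal plane in which
basal boundaries are seen. Real acquisitions vary per field of view; both
offsets are per-field configurable (`default_slabs()` arguments or explicit
`slab_spec()`).

## Cell segmentation and morphometry

Cortical actin renders cell boundaries as bright ridges; cells are the dark
basins between them. The pipeline is:

1. **Preprocessing.** Apical projections: morphological
   opening-by-reconstruction followed by closing-by-reconstruction with a
   disk element (radius 2 px by default) — flattens sub-element texture
   while preserving ridge geometry exactly. Basal projections: an adaptive
   local (Wiener-type) filter with a 5 px window — each pixel is shrunk
   towards its local mean in proportion to how much the local variance
   exceeds the estimated noise floor (the mean local variance). Both QC
   filtering and the same watershed are applied to apical and basal planes.
2. **Markers.** Regional minima of the boundary surface after h-minima
   suppression at depth `marker_h` (default 0.1 grayscale units). Deeper
   `marker_h` merges shallow minima and prevents over-segmentation from
   texture inside cells.
3. **Watershed.** Meyer flooding from the markers with 4-connected basins,
   which leaves 8-connected one-pixel watershed lines (label 0). A uniform
   image degrades to a single field-covering label with a warning rather
   than failing mid-pipeline.
4. **Ridge QC.** Each ridge separating two labels is scored by tortuosity
   (traced path length / endpoint chord; a straight ridge scores exactly
   1), physical length, and mean underlying image intensity. Ridges that
   are too tortuous (> 1.6), too short (< 3 µm) or strictly dimmer than
   the 30th percentile of all ridge intensities are dissolved by merging
   their two cells. The thresholds exist because the procedure requires
   them; all three are configuration, not fixed truth, and the intensity
   percentile can be set to 0 to disable that cut (e.g. for noise-free
   synthetic fields whose ridges are equally bright by construction).
5. **Area filter.** Cells outside [10, 2000] µm² (configurable) are
   removed as under-/over-segmentations.
6. **Morphometry.** Each cell gets the ellipse with identical normalized
   second central moments; the aspect ratio is the major/minor axis ratio.
   The per-pixel 1/12 variance term is included, so a 40×20 px rectangle
   yields AR = 2 exactly and a single pixel yields AR = 1. Density is
   cells per mm² over the full field of view by default (a
   `density_denominator = "segmented"` switch divides by summed cell area
   instead, since the choice of denominator is ambiguous in the source
   procedure). Per-field summaries are unweighted means over retained
   cells.

## Stress-fiber tracing

Fiber segmentation must cope with crossing fibers. The tracer works on a
ridge-enhanced image (maximum over 12 oriented line-mean filters of length
1.5 µm, lightly smoothed), thresholded (Otsu by default) and thinned to an
8-connected skeleton. The skeleton is decomposed into arcs at junction
pixels (Rutovitz crossing number ≥ 3, or ≥ 5 neighbours for the dense
diamond patterns thinning produces at right-angle crossings). Short
junction-to-junction arcs are crossing debris — the small bar thinning
leaves between two crossing thick strokes — and are absorbed into junction
clusters. Arm ends incident to a cluster are then paired by angular
continuation (mismatch ≤ 40°), so two crossing fibers are reassembled into
two straight fragments rather than four arms; junction clusters with no
arms (compact blobs left by very short fibers) are emitted along their
principal axis instead of being dropped. Fragment polylines are simplified
(Douglas–Peucker, tolerance ≈ 1 px) and each tip is extended along its
tangent to the half-maximum intensity point, which for a stroke convolved
with the imaging point-spread function is the fiber end. Fragments shorter
than 1 µm are discarded.

Fragment joining evaluates all endpoint pairs within a 3 µm gap; a pair is
joinable when the end tangents are anti-parallel within 20°, the connector
direction deviates less than 20° from both tangents, and — the intensity
continuity constraint — the mean intensity along the straight connector is
at least 0.6 of the dimmer fragment's mean. Candidates are scored (smaller
gap and smaller angle are better) and accepted greedily with deterministic
tie-breaks, each endpoint used at most once. Joined chains become single
fibers whose length is the sum of fragment lengths plus connector gaps.

Mean fiber length is the unweighted mean over fibers; total-length density
is the summed length divided by the searched area (µm⁻¹). When cortical
actin is present (jammed condition), the basal boundary ridge set dilated
to 1.5 µm is masked out first and subtracted from the searched area;
masking is a per-run flag because unjammed fields need no mask.

## Orientation fields and Alignment AUC

Local fiber orientation is estimated per 3×3 µm subregion from the
structure tensor of central-difference intensity gradients: the fiber
orientation is the eigenvector of the smaller eigenvalue (along the ridge,
perpendicular to the dominant gradient). The one-pixel image border is
excluded from the tensor sums so border subregions are not skewed by
one-sided gradients. Subregions overlapping masked boundaries, with mean
intensity below the 35th percentile of subregion means (computed on the
boundary-free image), or with negligible gradient energy are masked
invalid, never zero-filled.

The alignment statistic: for every pair of valid subregions within 50 µm,
alignment = cos 2Δθ, binned by centre distance (1 µm bins) and averaged
per bin. The null curve repeats this after randomly repositioning the
orientations over the valid positions — a permutation, conserving the
orientation multiset — averaged over 20 replicates. The **Alignment AUC**
is the trapezoidal area between the experimental and null curves: zero for
a uniformly aligned field (the curves coincide identically), near zero
(within repositioning noise) for spatially independent orientations, and
increasing with the spatial correlation length of alignment. The area has
units of µm; a normalization by the squared maximum distance is available
as an option but off by default, and the per-replicate spread of the null
area is reported (`null_auc_sd`) so an observed AUC can be judged against
repositioning noise.

## Migration speed

Dense optical flow between consecutive phase-contrast frames uses
polynomial (quadratic) expansion under Gaussian applicability: each frame
is locally approximated by a quadratic form, and the displacement field
follows from the shift between the two expansions, aggregated over a
Gaussian integration window (σ = 6 px), refined iteratively (3 iterations)
over a 3-level image pyramid with warping. Defaults
(`flow_params()`) suit the 0.5–2 px/frame displacements of epithelial
time-lapses.

Trajectories are seeded on a 10 µm grid and forward-integrated by bilinear
sampling of the per-interval displacement at the current position.
Trajectories leaving the frame freeze and are excluded from means. The
speed of a seed is its **net displacement** (start to end) divided by the
elapsed time — a closed loop has speed zero — matching the low speeds
expected of jammed controls; a summed path-length alternative
(`measure = "path"`) is provided. The field mean is the unweighted mean
over retained seeds.

## Statistics

Per-field metrics are aggregated as unweighted means (fields of view, or
wells = mean over each well's fields; missing fields are dropped with `n`
recorded). Group comparisons use one-way ANOVA with the Tukey–Kramer
honest-significant-difference adjustment (valid for unequal group sizes)
at α = 0.05; when every group has zero variance the degenerate results are
defined explicitly (equal means: F = 0, p = 1; differing means: F = ∞,
p = 0). Correlations are Pearson's r with the two-sided p-value.
Dispersion is reported as mean ± s.d.

## The synthetic generators

The generators are first-class, tested code; their defaults are the study
conditions of the package's benchmark suite.

**Cell fields.** A Poisson-disk-seeded Voronoi tessellation with two Lloyd
relaxation iterations (avoids sliver cells), rendered as bright boundaries
(with a small Gaussian blur mimicking diffraction) on dark interiors over
the 563×356 µm field at 1 µm/px. Elongation is imposed by measuring
seed–pixel distances in a frame stretched along x by `target_ar`, which
gives an analytic elongation axis; the true mean aspect ratio is
monotonically increasing in `target_ar`, with isotropic fields averaging
AR ≈ 1.3 (Voronoi cells are near-round, not circles). Ground truth — the
label map and per-cell moments — comes from the generator's internal
assignment, never from rendered pixels.

**Fiber fields.** Straight segments with Gaussian-distributed lengths
(default mean 3 µm, s.d. 0.5 µm, truncated at 0.5 µm), rendered as strokes
convolved with a Gaussian point-spread function (0.5 µm FWHM), composited
with per-pixel maxima so crossings stay intensity-continuous. Midpoints
are resampled so whole fibers lie inside the field; rendered foreground
then scales linearly with true total length. Orientation modes: i.i.d.
uniform, globally aligned, or patchwise aligned (all fibers whose midpoint
falls in a square patch share that patch's orientation, giving a
controllable orientation-correlation length; patch orientations can be
forced for fixtures). The default benchmark field is 200 fibers in
200×200 µm at 0.2 µm/px — a density at which 0.5 µm strokes remain
individually resolvable at Nyquist-scale sampling, which is what a
recovery benchmark of the tracer (rather than of the optical resolution
limit) requires.

**Time-lapses.** A fixed random texture advected by an analytic flow —
static, uniform translation, rigid rotation, or a swirl whose angular rate
decays with radius. All supported flows preserve radius or are uniform, so
the backward advection map is closed-form and frames are rendered exactly;
the analytic trajectory and speed of any point are exported. Displacements
above 25% of the field per frame are rejected as unrecoverable. The
default sequence matches the live-imaging protocol: 16 frames at 6 min
over 1.5 h.

**What passing recovery tests do and do not show.** The generators emulate
geometry, calibration, blur, and additive Gaussian noise (clipped to the
valid range). They do not emulate uneven illumination, pseudostratified
3D scattering, nuclei, photobleaching, or segmentation-confounding
debris. Real F-actin staining puts cortical boundaries and fibers in one
channel; the generators keep them in separate images because the relative
channel intensities are unspecified — a combined image is obtained by
per-pixel maxima of the two renders when a single-channel fixture is
wanted. Passing
parameter recovery therefore demonstrates correctness of the estimators
under known imaging physics, not robustness to every artifact of real
micrographs; the QC thresholds and tracer parameters exposed in
configuration are the intended handles for real data.

## Numerical choices and edge cases

- Reconstruction filters, h-minima, watershed, thinning and component
  labelling are exact integer/float morphology in compiled code;
  watershed flooding breaks ties by insertion order, so segmentation is
  deterministic.
- Connectivity: 4-connected cells, 8-connected ridges and skeletons.
- Areas are pixel counts × pixel area; no boundary-sharing correction.
- Degenerate inputs are defined, not crashed: uniform image → one label
  (warning); empty fiber set → density 0, mean missing; single-pixel
  region → AR 1; all-excluded trajectory set → error naming the cause.
- All randomness flows through explicit integer seeds; identical seeds
  give bit-identical images, truth tables and statistics.
- Benchmark problem sizes (100-cell fields, 200-fiber fields, 240×240 px
  alignment fields, 16-frame 256×256 px time-lapses, 2000-replicate
  statistical calibrations) were chosen so the full suite exercises every
  stage end-to-end in a few minutes on one CPU.

## Known limitations

- The fiber tracer resolves crossings down to ≈30° between strokes;
  shallower crossings can merge into kinked chains. Recovery of
  total-length density is biased a few percent low in dense fields where
  strokes fuse below the resolution limit.
- The basal-plane depth of real stacks varies by field of view; fixed slab
  windows approximate a per-field manual choice and should be overridden
  per field when metadata allow.
- The Alignment AUC is reported as an area over distance (µm). Reports
  that quote it in µm⁻¹ imply a normalization that is not part of the
  statistic's definition here; the optional `normalize = TRUE` divides by
  the squared maximum distance instead and is clearly labelled.
- Optical flow assumes displacements small relative to the texture
  correlation length; the generator enforces the 25%-of-field bound and
  the flow defaults handle up to a few px/frame.

## A worked synthetic example

```{r example, eval = FALSE}
library(ujtmorph)

# elongated epithelium: generate, segment, measure
cf <- generate_cell_field(cell_field_spec(n_cells = 100, target_ar = 2,
                                          rng_seed = 7))
seg <- segment_cells(projection(cf$image, "apical", 1))
cell_morphology(seg)$summary

# stress fibers: trace, join, summarize
ff <- generate_fiber_field(fiber_field_spec(rng_seed = 11))
fp <- projection(ff$image, "fiber", ff$spec$pixel_size_um)
fs <- join_fragments(trace_fragments(fp), fp)
length_metrics(fs)

# migration: synthesize a translating layer and recover its speed
tl <- generate_timelapse(flow_spec("translation", speed_um_per_h = 4))
mean_speed(integrate_trajectories(compute_flow(tl), 10))
```
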