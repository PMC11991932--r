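---
title: "Measuring urinary stone size on CT: the model behind stonesizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring urinary stone size on CT: the model behind stonesizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stonesizer)
```

## The measurement problem

A urinary stone's largest axial diameter, in millimetres, is the quantity
clinicians read off CT to decide between watchful waiting and intervention.
Two physical effects corrupt it in opposite directions. *Partial volume*:
a voxel straddling the stone boundary averages stone and water attenuation,
so faint stones (around 100 HU, e.g. uric-acid-like compositions) blur into
the background and read small. *Blooming*: very dense stones (around
3000 HU) scatter apparent attenuation beyond their physical boundary and
read large. Between the two, common ~1000 HU calcium stones are measured
best. `stonesizer` implements an automated measurement algorithm, a digital
phantom study for exercising it under controlled versions of those effects,
and the statistics of a multi-reader accuracy study.

## The automated measurement model

The **detector** thresholds the volume at `hu_threshold` (default 80 HU),
labels the 3D foreground into connected components, drops components
smaller than `min_voxels`, and crops a region of interest (ROI) around each
survivor. The threshold sits below the faintest stone class studied
(~100 HU) but far above water (0 ± 7 HU) and the latex tube wall
(10–20 HU). Connectivity defaults to 26 neighbours, the usual choice for
blob isolation; all three neighbourhoods (6/18/26) are supported and tested
against an independent flood-fill oracle. `min_voxels = 4` suppresses
single-voxel noise yet keeps a 1.4 mm stone, which spans about 4–6 voxels
at the default spacing. The ROI margin of 5 voxels guarantees the
measurer's rays traverse genuine background beyond the stone.

The **measurer** works per axial ROI slice:

1. the stone centre is the binary centroid of the candidate mask on that
   slice (a fixed 3D centroid is available via
   `measurer_config(centre = "fixed-3d")`; the per-slice centroid is the
   default because it tracks slight axial tilt of a real stone);
2. `n_rays = 360` rays leave the centre at 1° spacing; HU are sampled by
   bilinear interpolation every `sample_step = 0.5` in-plane pixels, with
   physical positions accounting for anisotropic spacing;
3. the first-order Haar differential filter `response[i] =
   samples[i+1] - samples[i]` is applied; its most negative value beyond
   `min_radius = 0.5` mm (so the stone's flat top cannot win the arg-min)
   marks the edge. A ray yields no edge when that minimum is shallower than
   `-tau` (default 30 HU per sample) — the profile then has no material
   descent, as happens when blur flattens a faint stone's gradient below
   the noise;
4. the edge position is the midpoint of the minimizing sample pair,
   refined to sub-sample precision by a parabolic fit over the minimum and
   its neighbours (`refine = TRUE`); the refinement offset is clamped to
   half a step so a degenerate fit cannot move an edge across samples;
5. the per-slice size is the maximum pairwise Euclidean distance between
   edge points in millimetres; slices with fewer than 3 edge points are
   skipped with a recorded reason; the reported stone size is the maximum
   over usable slices.

Two open points were settled as follows. The published description of the
measurer mentions an internal bone-like display window written "(500,
1600)" without naming which number is the width; since the standard bone
window is width 1500 / level 600, we read it as level 500 / width 1600
(the opposite reading would hide every stone below 1350 HU and is plainly
not meant, though it remains selectable). The measurer nevertheless
operates on raw HU by default: the arg-min of the Haar response is
invariant to the window's affine rescaling, and window *clipping* would
move the apparent edge of very dense stones outward, conflating display
with physics. Passing `measurer_config(edge_window = "measurer_bone")`
reproduces the display-faithful variant. Second, each ray contributes at
most one outline point; multiple minima along a ray would imply nested
edges, which cylinders do not have.

## What the phantom generator emulates

`rasterize_scene()` renders cylindrical stones, a tube wall, and a water
bath on the voxel grid by supersampled volume-weighted averaging (3³
sub-cells per voxel): this *is* the partial-volume model, and it conserves
attenuation mass to within 2% of the analytic cylinder volume. Stones lie
with their axis along the slice normal, so axial sections are discs whose
diameter is the measured quantity — matching the physical phantoms, which
were positioned perpendicular to the scan plane and appeared round on
axial images. Arbitrary axes are supported for tilt experiments.

Geometry and spacing follow the physical study where stated: 1.0 mm slice
thickness, three densities ≈100/1000/3000 HU, eight diameters 1.4–8.6 mm,
a 10–20 HU tube, water within 0 ± 7 HU, 24 stones across six tubes with
four per tube and centre spacing at least twice the largest diameter. The
printed size column of the study's variability table lists 6.6 mm twice in
its 100 HU block where the other blocks list 5.2 then 6.6; we treat that
as a typographical duplication and use the common 8-size set
`r paste(stone_sizes(), collapse = ", ")` mm for all densities, while
`reference_stone_errors()` preserves the values verbatim.

Where the study is silent we chose once and fixed the value:

* **in-plane spacing 0.7 mm** — a typical abdominal CT pixel;
* **PSF sigma 0.5 mm** (axial and in-plane; FWHM ≈ 1.2 mm, a standard
  abdominal reconstruction). This value also calibrates the twin to the
  *reported* degradation pattern: at 0.5 mm the 100 HU stones'
  Haar-response amplitude sits near τ, so some rays and the smallest
  stones drop out and the automated model underestimates faint stones, as
  the physical study observed. Much below 0.4 mm the faint stones are
  measured almost perfectly (unlike the physical study); much above
  0.55 mm most of the 100 HU class becomes unmeasurable;
* **noise sd 5 HU** — water-bath noise of a standard-dose abdominal
  protocol; the simulated water region then trivially satisfies the
  0 ± 7 HU acceptance band on its mean;
* **stone length 10 mm** and tube-slot spacing 30 mm, comfortably
  satisfying the separation constraint;
* **blooming** is phenomenological: the ≥1500 HU component is dilated
  in-plane with radius `0.8 mm per 1000 HU` of peak density above the
  threshold, blurred by an extra 0.3 mm, and amplified by a rim gain of
  0.3. Dilation is the essential ingredient: extra blur alone does not
  move a profile's steepest descent (a blurred edge keeps its inflection),
  so a blur-only blooming model cannot reproduce the overestimation of
  dense stones under a gradient-based edge rule. The dilation uses
  bilinear sub-voxel shifts so radii below one pixel still act. Blooming
  is **off by default** — the default acquisition represents a
  well-corrected scanner — and enabled explicitly for artifact
  experiments.

All randomness (stone-to-tube assignment, noise, rater panels) flows from
explicit integer seeds; rerunning with the same seed reproduces volumes
bit for bit.

What the generator does *not* emulate: projection-domain physics
(sinograms, filtered backprojection, beam-hardening streaks, kVp/mAs noise
scaling), irregular stone shapes and compositions, patient anatomy, or
reader psychology beyond a per-cell bias + Gaussian noise model. Passing
tests on synthetic scenes therefore demonstrates algorithmic correctness
and directional artifact behaviour, not clinical performance.

## Evaluation statistics

The unit of analysis is the per-rater MAE over the eight stones of one
density, matching a reader study that reports "mean ± sd over 52
participants". Manual-vs-manual comparisons use a paired two-sided
Student's t-test on per-rater MAEs (Welch is available); manual-vs-
automated uses a one-sample t-test of the manual per-rater MAEs against
the automated MAE, since the automated method contributes a single value
per density — the published analysis does not state its construction, so
this interpretation is explicit and selectable. "Raters beaten" counts
strict inequalities; ties are not wins. Display rounding is 2 decimals for
MAE and 1 for percentages; full precision is kept internally. Degenerate
paired inputs (identical MAE vectors) return t = 0, p = 1 rather than an
error. No multiple-testing correction is applied, as none is described
for the original analysis.

## Numerical choices and degenerate inputs

* Voxel order is `[z, y, x]`, 1-based, with inclusive bounding boxes —
  R's native convention; ROI cropping round-trips indices exactly.
* Component labels are assigned by decreasing voxel count with
  lexicographic tie-break, making outputs reproducible.
* DICOM slices are ordered by the projection of the image position onto
  the slice normal, never by file name or instance number; inter-slice
  spacing comes from adjacent sorted positions, falling back to the
  slice-thickness tag (with a warning) only for single-slice series.
* Rays are cut at the ROI boundary; the common ray-fan implementation
  masks out-of-slice samples rather than growing ragged arrays.
* An empty mask slice, a slice with < 3 edge points, and a candidate with
  no usable slice are three distinct failures: skip, skip with reason,
  and an error carrying the candidate id (downstream, `measure_stones()`
  converts the last into `NA` + note so one faint stone cannot abort a
  study run).

## Problem sizes used by the test suite

The suite runs the full 6-tube study (about 190 × 43 × 43 voxels per tube)
a handful of times: once noiseless, once under the default acquisition,
and twice with blooming enabled for the directional checks; oracle
equivalence uses 200 random 12³ masks across the three connectivities.
These sizes keep a complete run in the low minutes on one CPU while
exercising every stone class of the study design.

## Known limitations

The reported size is a per-slice in-plane maximum; oblique or 3D maximal
diameters and volume estimation are out of scope. The detector separates
stones from a clean background only — distinguishing stones from bone or
vascular calcification in real anatomy is explicitly not attempted. The
twin's 100 HU degradation is somewhat stronger than the physical study's
(its smallest faint stones can fall below the detection threshold
entirely), which we accept rather than tune away, since the direction and
ordering of the density effects are the properties the package asserts.
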