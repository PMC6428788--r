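---
title: "Planning intramyocardial injections from LGE-MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning intramyocardial injections from LGE-MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cartoplan` plans catheter injections into the border zone of a
myocardial infarct from segmented LGE-MRI, registers the plan to an
interventional epicardial surface, and evaluates retrieved injections
the way a histological validation study would. This vignette records
the models, every tunable that matters, and the reasoning behind the
numerical choices — including what the synthetic phantom does and does
not establish about real data.

## The planning model

**Inputs.** Per-slice closed endocardial and epicardial contours of the
left ventricle in patient coordinates (mm), the matching short-axis LGE
intensity volume, and the in-slice direction of the septum. All patient
coordinates are DICOM LPS millimetres; NIfTI input/output converts from
RAS at the boundary. Slices are indexed apex to base, angles measured
counter-clockwise from the +x axis about the slice's endocardial
centroid, indices in exported JSON are 0-based.

**Scar segmentation (FWHM).** Enhancement is thresholded at half
maximum over the myocardial intensities of each slice, referenced to
the myocardial minimum:

$$T = I_{\min} + \tfrac12\,(I_{\max} - I_{\min}),\qquad
\text{scar} = \{\,\text{myocardial pixels with } I \ge T\,\}.$$

The rule is applied per slice because enhancement scaling drifts
between slices in practice; a per-volume threshold and a plain
$0.5\,I_{\max}$ reference are available as options
(`scope = "volume"`, `reference = "max"`). Published FWHM descriptions
differ on the reference; the min-referenced range variant was chosen
because it is invariant under affine intensity changes. Connected
components below `min_component_px = 5` pixels are discarded — a
single-pixel speckle at typical LGE resolution is noise, not infarct.
No interactive seed region is used: the pipeline is deliberately
non-interactive. A slice with constant myocardial intensity carries no
enhancement information and yields an empty mask with a warning rather
than an error.

**Surface mapping.** Each endocardial contour is resampled to
`points_per_slice = 120` vertices (3° angular resolution — smooth
enough that the 1–20% band is several vertices wide on a 60° scar,
coarse enough that toy meshes stay readable) at equal arc length,
starting where the angle-0 ray from the centroid crosses the contour;
adjacent rings are triangulated by index correspondence. At each vertex
the outward in-slice normal is estimated from the two neighbouring
vertices (central difference, sign-oriented away from the centroid) and
cast against the epicardial contour:

* **wall thickness** WT = distance along the normal to the first
  epicardial crossing (falling back to the centroid-through-vertex ray
  for strongly non-convex contours, and erroring with slice and angle
  if both miss);
* **transmurality** T = percentage of that same chord intersecting the
  scar mask, sampled at steps of a quarter pixel (midpoint rule).

Chords are cast in-slice (2-D) because the measurement convention of
the validation endpoint — depth and wall thickness perpendicular to the
endocardial contour on short-axis sections — is two-dimensional, and a
3-D chord family would require a long-axis definition that contour
stacks do not carry. Scalars live on vertices, not faces, because
targets and distances are point quantities.

**Planner.** The infarct border zone (IBZ) is
$\{1\% \le T \le 20\% \ \wedge\ \mathrm{WT} > 5\,\mathrm{mm}\}$ (band
bounds inclusive); danger zones are $T > 20\%$ (dense scar) or
$\mathrm{WT} < 5\,\mathrm{mm}$ (perforation risk); a wall of exactly
5 mm is neither. 16 targets are split 8/8 between the septal and
anterior sides — a vertex is septal when its in-slice direction lies
within 90° of the user-supplied septal direction, boundary inclusive.
"Equally distributed" is realised as greedy farthest-point sampling
per sector under the 3-D Euclidean metric, seeded at the IBZ vertex
nearest the sector's angular centre: the greedy rule is deterministic,
needs no tuning, and carries the classical factor-2 dispersion
guarantee. Needle depth is half the local wall thickness
(`needle_depth_fraction = 0.5`), the convention for setting needle
extension from MRI wall thickness.

**Export.** Each target becomes a separate DICOM series sharing the
base volume's geometry — the target voxelised as a 2 mm sphere at
maximal intensity over a subsampled endocardial point cloud — plus a
JSON sidecar carrying the exact coordinates, sector and needle depth.
The voxelised-marker-plus-sidecar encoding was chosen over RT-Structure
because it is viewer-agnostic and the sidecar is loss-free; the DICOM
writer produces plain explicit-VR little-endian secondary-capture
objects that any DICOM implementation reads.

## Registration

The interventional reconstruction provides an epicardial surface point
cloud in its own frame. Alignment is rigid only — both modalities are
metric — and proceeds in two stages mirroring the clinical workflow of
a rough anatomy-based fusion refined on the cardiac contour:

1. **Coarse**: centroids and principal axes are matched; the four
   proper axis-sign combinations are disambiguated by symmetric
   nearest-neighbour RMS. This stands in for the interactive
   workstation pre-alignment; its contract is only to be good enough
   for ICP.
2. **Trimmed ICP**: point-to-point correspondences, per-iteration
   closed-form rigid fit (SVD of the trimmed cross-covariance), keeping
   the best 80% of matches (`trim_fraction = 0.2`) against partial
   coverage; stop when the trimmed RMS improves by less than
   `tol = 1e-4` mm or at `max_iter = 100`.

Two numerical choices deserve note. The ventricular surface is close to
a surface of revolution, so the ICP cost is shallow along rotations
about the long axis and point-to-point ICP can settle a few degrees
off. `register_to_ra()` therefore (a) denoises the target cloud by
averaging each point with its 6 nearest neighbours — the angiographic
side is the noisy one, and at the cloud densities involved the
curvature bias of this smoothing is below 0.1 mm — and (b) probes small
rotations (±2.5°, ±5°, ±8°) about the target's principal axes with
short trimmed-ICP runs on subsampled clouds, fully refining the few
best basins and keeping the lowest trimmed RMS. Both steps are plain
robustifications of the stated two-stage procedure, not extra degrees
of freedom. The trimmed RMS is non-increasing across iterations by
construction (re-matching cannot increase any point's distance, the
trimmed subset cannot exceed the previous kept sum, and the closed-form
fit minimises over the kept pairs); the test suite asserts this trace
property on every registration it runs.

## Evaluation endpoints

The primary accuracy endpoint of a validation study is the **signed
distance of each injection to the IBZ, measured along the endocardial
contour** of its slice: the injection is projected onto the endocardial
ring, transmurality is interpolated linearly between ring vertices, and
the minimal arc length to the in-band arc is computed, 0 inside. The
sign convention is inferred from how such results are reported
(injections "inside" the zone at negative millimetres): **negative =
the nearest zone boundary is an upper-bound crossing (dense-scar
side), positive = lower-bound crossing (remote side)**. Distances stay
on the 2-D contour of one slice — matching measurement on sectioned
histology — and when an injection's slice has no border zone, the
nearest slice with one is used, with the out-of-plane offset reported
separately rather than folded into the distance. Injection **depth** is
the perpendicular point-to-contour distance, positive into the wall,
negative (with a warning) on the blood-pool side.

Repeated measurements are averaged per animal before any comparison, so
the animal is the statistical unit; the group grand mean is the mean of
animal means, not the pooled injection mean. Group comparisons use the
unpaired two-tailed t test. Because published tables report mean ± SD,
the test is implemented directly from summary statistics; the pooled
variant is the default since recomputation of the published procedure
tables from their printed summaries reproduces the printed p-values
under pooling (e.g. 0.355 for injection-procedure time, 0.031 for dose
area product per injection). Some printed values sit closer to the
Welch variant, and the inputs are rounded to one decimal, so exact
reproduction of every cell is not expected — both variants are
exported. Shapiro–Wilk and the 2×2 Pearson chi-square (no continuity
correction) delegate to the standard `stats::` implementations.

## The synthetic phantom

`generate_phantom()` emulates the full study substrate with exact
analytic truth. The left ventricle is a stack of `n_slices = 10`
short-axis annuli at 5 mm spacing; the endocardial contour of slice
$k$ is $r(\theta) = R_k (1 + e \cos 2\theta)$ with $R_k$ tapering
16→22 mm apex to base, and the epicardial contour is its **exact
outward offset** at 10 mm, so true perpendicular wall thickness is
exactly the nominal value. The scar is a 60° wedge straddling the
antero-septal junction whose transmurality profile falls linearly from
100% at the wedge centre to 0% at the edges; voxels take 300 a.u. in
scar, 100 a.u. in remote myocardium (the 3:1 contrast is a free choice;
LGE appearance is not otherwise specified anywhere authoritative),
30 a.u. background, plus Gaussian noise of sd 10 and rounding to
integer magnitudes. In-plane pixels are 0.8 mm — a high-resolution
pre-clinical LGE grid at which chord discretisation (±1 pixel over a
10 mm wall, i.e. ±8 percentage points worst case) still leaves the
1–20% band several vertices wide per slice. Voxel classification
inverts the offset-curve geometry by Newton iteration on the analytic
contour, so truth masks are exact to ~1e-10 mm.

Two departures from the simplest circular-annulus design are
deliberate: a small cross-sectional ellipticity ($e = 0.12$) and a
quadratic 3 mm in-plane drift of the slice centres toward the base. A
perfectly circular straight tube is rotationally symmetric, which makes
the in-plane component of any rigid registration of its epicardial
surface mathematically unidentifiable — no algorithm could recover it,
and nothing about real ventricles is symmetric in that way. The
ellipticity breaks the continuous symmetry and the centre drift breaks
the residual 180° symmetry, keeping the registration problem the
phantom poses well-posed while leaving the wall-thickness and
transmurality truths exact (the epicardium remains an offset curve).

The interventional cloud (`generate_ra_cloud()`) samples the epicardial
truth densely (400 points per slice, mirroring a surface
reconstruction), applies a known rigid transform, adds isotropic
0.5 mm jitter and randomly keeps 70–100% of points.

**What phantom results do and do not show.** Passing tests establish
that the implementation is correct against analytic geometry:
thresholding, chord integration, dispersion, registration and arc
distances do what their definitions say. They do not establish clinical
performance: the phantom has no papillary muscles or trabeculation, no
partial-volume or Rician intensity statistics (Gaussian noise is
sufficient for a threshold/geometry pipeline, not for MR magnitude
realism), no motion, no segmentation error in the contours, and its
scar is a single smooth wedge rather than a patchy infarct. Real
registration also faces thoracic structures absent here.

## Degenerate inputs and tie-breaks

* Contours: at least 8 points, implicitly closed; an excessive closing
  gap (> 5× the median edge) is rejected as an open trace, as are
  self-intersections, naming the slice.
* A wall chord that misses the epicardium by both the normal-ray and
  centroid-ray strategies errors with slice and angle.
* Sector ties (vertex exactly on the septal/anterior boundary) go to
  septal; farthest-point ties go to the lowest vertex index, making
  plans bit-reproducible.
* Transmurality exactly 20% is border zone (inclusive band); wall
  thickness exactly 5 mm is neither border zone nor danger.
* Degenerate t-test input (both SDs zero) yields p = 1 on equal means,
  p = 0 with a warning otherwise; rank-deficient point clouds fall back
  to centroid-only coarse alignment with a warning.

## Problem sizes used by the test suite

The suite runs phantoms of 3–10 slices on 0.2–0.8 mm grids, 100 random
arc-distance toys against an exhaustive dense-resampling search, 20
registration seeds at 0.5 mm noise and 70% coverage, and 1000-replicate
null calibrations of the t test — sizes chosen so that every check
exercises the full code path at meaningful resolution while the whole
suite stays comfortably runnable on a laptop.
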