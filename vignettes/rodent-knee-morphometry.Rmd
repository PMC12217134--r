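---
title: "Morphometry of rodent knee soft tissues: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of rodent knee soft tissues: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodentmorph)
```

## The measurement problem

High-field MRI of rat and mouse knees yields manual segmentations of the
four primary ligaments (ACL, PCL, MCL, LCL) and the two menisci, exported as
triangle surface meshes (STL, millimetres). From those surfaces this package
computes three families of quantities:

* **Ligament cross-sectional area (CSA).** The surface point cloud is
  centered and rotated so the ligament's longitudinal axis lies on +z, then
  cut into fixed slabs (0.1 mm for rat, 0.05 mm for mouse — the source voxel
  sizes). Each slab is flattened along z and its CSA computed. The
  *midsubstance CSA* averages the slabs whose centers fall in the middle 50%
  of the length, excluding the flared bony insertions whose geometry is
  dominated by the attachment, not the ligament proper.
* **Normalized CSA.** CSA as a percentage of the tibial plateau footprint —
  the area of a single axial tibia slice segmented at the widest point of
  the plateau, computed as `n_voxels * voxel_size^2`. This makes rat and
  mouse ligaments comparable on a common bone-size scale.
* **Meniscal regional geometry.** Each meniscus, expressed in anatomic axes
  (x medial–lateral, y posterior–anterior, z distal–proximal), is measured
  at three regions: the circumferential apex (*central*, three coronal
  slabs) and the two free ends (*anterior/posterior horn*, three sagittal
  slabs). Within each flattened slab, ten equally spaced stations record
  the horizontal and vertical spans; a per-slice width/height is aggregated
  over stations and the region value is the mean over its three slices.

A validation stage mirrors the measurement-agreement analyses that
accompany such a pipeline: Bland–Altman bias and 95% limits of agreement,
the two-way absolute-agreement single-score ICC, Kruskal–Wallis and rank-sum
tests with Bonferroni correction, an aligned-rank-transform (ART) two-way
factorial analysis, and Shapiro–Wilk/Bartlett gating.

## Alignment

The longitudinal axis is the first principal direction of the centered
vertex cloud (SVD). Principal directions are sign-ambiguous, so the frame is
made deterministic: the z sign is chosen so the skewness of the aligned z
coordinates is nonnegative, the second direction's largest-magnitude
component is made positive, and the third completes a right-handed frame.
Alignment refuses clouds whose first principal extent is less than 1.2 times
the second (`align_longitudinal(min_extent_ratio = )`): for a near-isotropic
cloud the "longitudinal axis" is noise.

## Slab CSA: two estimators

`slice_profile()` bins points into half-open slabs `[z_lo, z_lo + dz)`
anchored at the minimum z; a trailing partial slab is kept only if it holds
at least 3 points, and an interior slab with fewer than 3 points gets area 0
with a warning. Two CSA estimators are provided:

* `hull` (default): area of the 2D convex hull of the slab's points
  projected along z. This is the natural estimator for a point cloud and is
  exact for convex cross-sections in the dense-sampling limit.
* `plane_intersection`: the slab mid-plane is intersected with the surface
  mesh; crossing segments are chained into closed loops through shared mesh
  edges and the enclosed polygon area is summed, with nested loops (holes)
  subtracted by containment parity. This estimator is exact for any
  watertight mesh and serves as the geometric cross-check: on convex
  phantoms the two agree within 1% per slab, and on a crescent (non-convex)
  section the hull is provably an over-estimate, which the tests assert.

Flattening is orthographic along z with no obliquity correction; slabs are
thin relative to ligament curvature at these scales, and the paired
estimator quantifies the residual discrepancy.

## Meniscal regions

Region placement is driven by the oriented geometry itself. The central
region's coronal slabs are centered at the anterior–posterior position of
the circumferential apex — the lateral-most point for a lateral meniscus,
medial-most for a medial one. Horn slabs are sagittal and centered at the
mid-x of the horn's free-end lobe, where the horn is the set of points
beyond the cloud centroid toward anterior (or posterior) and the lobe is the
band of the horn within `max(1.5 * slice_thickness, 5%)` of its extreme y.
The lobe band is a documented heuristic: the free end of a C-shaped
structure has no landmark other than its extremum, and the phantom
generator records analytic horn coordinates precisely so this heuristic is
tested, not assumed.

Slice thickness defaults to the source voxel size (0.1 mm rat, 0.05 mm
mouse). Station aggregation defaults to `max`; `mean` is also available
because the two conventions coexist in practice (maximum span per slice
versus averaged span), and the choice is carried in the output so reports
are auditable. With ten stations on a dense elliptical section the max
aggregation underestimates the true diameter by under 1% (the outermost
station bin center sits 1/20 of the span from the edge), well inside the
3–5% tolerances used in the tests.

## Footprint and label volumes

`plateau_footprint()` enforces the single-axial-slice precondition and
reports `n_voxels * voxel_size^2` exactly; the error message names the
offending slice indices when the mask spans several. Label volumes are read
from NIfTI (via RNifti) or a minimal NRRD (ascii/raw encodings with a
`spacings` field), with a raw-text + JSON sidecar fallback; only isotropic
voxels are accepted because every increment in the pipeline is tied to the
voxel size. NIfTI writers drop trailing singleton dimensions, so
single-slice masks are padded with one empty slice on write; the occupied
voxels are unchanged.

`mesh_from_volume()` smooths the binary mask with an isotropic Gaussian
(sigma in voxels, default 1.0 — the smoothing conventionally applied to
segmentation masks before surface export) and extracts the 0.5 iso-surface
by marching tetrahedra on the Kuhn 6-tetrahedra decomposition, which tiles
space face-consistently and therefore yields watertight meshes. Two
numerical details matter and are tested:

* shared crossing edges are interpolated from the lower-index grid node so
  coincident vertices are bit-identical and the exact-match deduplication
  closes the surface;
* triangle windings are oriented toward the outside corners of each
  tetrahedron, so signed-volume computations are consistent.

At `sigma = 0` the exact voxel-boundary (cuberille) surface is emitted
instead: a single voxel becomes a cube of side `voxel_size` and the
enclosed volume equals the voxel-count volume exactly. This also gives the
intuitive staircase-versus-smooth behavior asserted in the tests: smoothing
reduces surface area and (for convex solids) monotonically shrinks enclosed
volume, by about 2–3% at sigma = 1 for a sphere ten voxels in radius.

`voxelize()` inverts the process for phantoms: a voxel is occupied iff its
center is inside the watertight mesh, decided by the parity of surface
crossings along each z column, with exact duplicate crossings (shared mesh
edges) collapsed.

## Statistics

Standard tests are delegated to base R (`kruskal.test`-equivalent midrank H
with tie correction, `wilcox.test`, `shapiro.test`, `bartlett.test`,
`TukeyHSD`, `p.adjust`); the package adds the glue and the pieces base R
lacks:

* `kruskal_wallis()` optionally computes a label-permutation p value, so the
  chi-square approximation can be compared against an exhaustive assignment
  oracle at small n (at n = 3+3+3 the chi-square approximation deviates
  from the exact tail by a few hundredths, which is why the option exists).
  All-tied inputs return H = 0, p = 1 by convention.
* `art_anova_2way()` implements the aligned-rank-transform factorial: for
  each effect the response is aligned (cell-mean residual plus that
  effect's marginal estimate), midranked, and a two-way fixed-effects ANOVA
  on ranks is read off for that effect only. The defining algebraic
  property — after aligning for one effect, the unranked ANOVA shows zero
  sums of squares for all other effects — is asserted to 1e-8 relative.
  The factors are treated as fixed effects; a repeated-measures treatment
  would need a specimen-level pairing structure that the measurement design
  here does not define.
* `icc_agreement()` is the two-way absolute-agreement single-score form
  ICC(A,1), built from the two-way mean squares; the consistency form is
  returned alongside because the distinction (a constant rater offset
  lowers agreement but not consistency) is exactly what the tests probe.
  Simulated raters with subject SD 2 and error SD 1 recover the analytic
  target 4/5 within ±0.05 at n = 200.
* `adjust_bonferroni()` is the capped multiply, applied to every post hoc
  family. Reported tables print p below 0.001 as "<0.001" but store full
  precision.

The gate (`normality_variance_gate()`) only recommends; the pipeline never
switches tests on its own, because silent test-switching makes reports
irreproducible.

For the ligament post hocs the default is Tukey's HSD on rank-transformed
data with pairwise rank-sum tests as the alternative; the meniscus post
hocs use pairwise rank-sum tests. Both routes are exposed because the two
conventions pair differently with a Kruskal–Wallis omnibus, and which one a
given report used is rarely stated; making both explicit keeps the choice
auditable.

## Synthetic phantoms

The generators in this package are first-class, tested code: they are the
only way to exercise the pipeline without animal data, which is not
publicly deposited for this kind of study.

* `make_ligament_phantom()`: watertight tube along an arbitrary axis;
  cross-section circle, ellipse, or crescent (outer disc minus an
  offset inner disc, with closed-form area); radius profile constant,
  linear, or flared at both ends. For circular sections the profile value
  is the radius in mm; for ellipse/crescent it is a dimensionless scale on
  the stated section. The manifest stores the analytic CSA(z) and the
  analytic midsubstance CSA.
* `make_meniscus_phantom()`: elliptical section (2a radial width, 2b
  height) swept along a circular arc; the outer fifth of the arc at each
  end carries a `horn_scale` multiplier. The manifest stores regional
  widths/heights and the apex/horn-end coordinates used by the
  region-selection tests.
* `make_footprint_mask()`: single-axial-slice ellipse (analytic area pi a b)
  or seeded smooth blob, by center-in voxel occupancy.
* `make_agreement_pairs()` / `make_cohort_table()`: Gaussian
  subject/rater/noise structure with the analytic ICC(A,1) target
  `sd_s^2 / (sd_s^2 + bias^2/2 + sd_e^2)` recorded, and tidy cohort tables
  drawn around supplied group means (e.g. the printed per-tissue means and
  SDs).

Every generator is deterministic given its arguments and `seed`; noise is
applied to measurement tables, not phantom vertices, unless vertex jitter is
explicitly requested. Default resolutions (about 2000 surface points per
mm², at least 100 points per slab; 181 arc rings and 64 section points for
the meniscus) were chosen so the discretization error of the phantoms is
several times smaller than the 1–5% tolerances being tested.

What the phantoms deliberately do not model: MRI signal formation, partial
volume and rater variability in segmentation, non-tubular ligament shape,
and ossicles or inhomogeneous tissue in the menisci. Passing phantom tests
therefore demonstrates that the geometry and statistics are computed
correctly, not that segmentations of real knees are accurate — the latter is
what the agreement stage (ICC, Bland–Altman against a second modality)
measures on real paired data.

## Degenerate inputs and tie-breaks

* Near-isotropic point clouds: degenerate-axis error rather than an
  arbitrary axis.
* Slabs with < 3 points: area 0 with a warning (interior) or dropped
  (trailing partial slab); empty station bins record span 0 with a warning.
* All-tied samples: H = 0 / p = 1; paired rank-sum on identical vectors
  returns p = 1; a constant agreement table is an error (ICC undefined).
* Footprint masks spanning several axial slices: error naming the slices.
* Vertex deduplication is exact, not tolerance-based, so STL round trips
  are bit-stable; geometry written as binary STL survives the float32
  format within 1e-6 mm.

## Problem sizes

The test-suite and acceptance runs use tube phantoms of 1–2 mm with
5k–15k vertices, meniscus phantoms with ~12k vertices, masks up to about
120^2 voxels per slice, 2000 replicates for the type-I calibration, and
n = 200 for ICC recovery. These sizes put the Monte-Carlo error of each
check well inside its asserted tolerance while a full run stays in the
tens of seconds.

## Known limitations

* The meniscal horn lobe heuristic assumes a C-shape opening along the
  anterior–posterior axis after orientation; a severely discoid or
  fragmented meniscus would need manual region placement.
* `plane_intersection` requires a watertight mesh; scanned surfaces with
  holes fall back to the hull estimator.
* The ART treats both factors as fixed effects (no repeated-measures
  correlation structure).
* Ligament length, orientation angles, insertion-site geometry, meniscal
  volume and circumferential length are out of scope.
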