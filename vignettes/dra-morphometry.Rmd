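---
title: "Methods: localizing and measuring the dorsal rim area in 2D and 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing and measuring the dorsal rim area in 2D and 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dramorph)
```

## The measurement problem

The dorsal rim area (DRA) is the polarization-sensitive dorsal patch of an
insect compound eye. In bumblebees it is visible as a grey region in
photographs of the dorsal head, but carries no contrast in micro-CT
reconstructions of the same head. Measuring it therefore requires joining
two modalities: a calibrated 2D photograph in which the DRA can be
annotated, and a 3D surface model on which areas, regions and internal
ommatidial structures can be measured. `dramorph` implements that join as
an explicit geometric pipeline — pose estimation from ocelli landmarks,
ray projection of the annotation onto the eye surface, and virtual
histology inside the volume — together with the statistical layer used to
interpret the measurements (2D-vs-3D equivalence, region contrasts,
allometry against body size).

## The phantom model

All validation rests on synthetic specimens with closed-form ground truth,
not on downloaded imaging data. The phantom eye is a sphere of radius $R$
(default 1.2 mm); the DRA is the spherical cap of angular radius $\theta$
about a chosen axis, with exact area

$$A_{\mathrm{DRA}} = 2\pi R^2 (1-\cos\theta),$$

and the whole-sphere eye area is $4\pi R^2$. The planimetric (projected)
area of the cap viewed pole-on is $\pi R^2 \sin^2\theta$, so the 2D/3D
ratio is $(1+\cos\theta)/2$ — about 0.98 at $\theta = 0.3$ and converging
to 1 for flat patches. This single closed form is what makes the sphere
cap a better phantom than a bumblebee-accurate ellipsoid: every area the
pipeline measures has an analytic oracle. The mesh itself is a subdivided
icosahedron (20480 faces at the default refinement), which recovers the
sphere area to 0.03% and the cap area to well under 1%.

Volume phantoms carry concentric shells inward from the eye surface —
lens, crystalline-cone layer, rhabdom layer, interior — at fixed
documented gray levels (5000 / 30000 / 22000 & 18000 / 45000 / 12000 on
the 16-bit scale), with optional Gaussian gray noise (default 2% of the
dynamic range). The cone layer carries an angular banding whose lateral
period is the cone width *at the cone layer's own mid radius*, so lateral
width measurements have a defined truth. The cone layer inside the DRA cap
can be built thinner (`dra_cone_scale`, default 0.8 in the validation
studies), emulating the contrast reported for bumblebees. A gap of known
arc length can be cut into the rhabdom shell to exercise the continuity
QC.

Two scales are used deliberately. Mesh-level phantoms (areas, pose,
overlay, the 2D-vs-3D cohort) are paper-scale ($R \approx 0.8$–$1.4$ mm).
Volume phantoms are miniaturized ($R \approx 0.16$–$0.23$ mm at the
instrument voxel size of 1.625 µm, layers 18/36/50 µm, facet pitch 8 µm)
so that a whole eye fits in a $\sim 200^3$–$260^3$ voxel volume while
every layer still spans more than ten voxels. The miniaturization changes
no algorithm and no relative tolerance; it keeps full-volume studies
repeatable on a desk.

What the phantoms do *not* emulate: pile (hair) occluding the ocelli,
pigmentation gradients, staining artifacts, reconstruction noise
correlations, and non-spherical eye shape. Passing tests therefore show
that the geometry and measurement chain is correct, not that manual
annotation of difficult real images is easy.

## 2D planimetry

Calibration fits a similarity transform (isotropic scale + rotation +
translation) from grid-lattice mm coordinates to clicked pixel positions,
by least squares on complex coordinates. A similarity, not an affine, is
used because the grid is assumed to lie in the focal plane; the RMS
residual is reported so a tilted grid shows up as a bad fit rather than a
silent bias. The grid pitch is a required input — it is a property of the
grid paper, not something the data can reveal. Area measurement is plain
pixel counting at pixel-center membership times `mm_per_px`²; no sub-pixel
boundary smoothing is attempted (the bias is below 1% for masks of
10⁴ px and above). Size classes use the study's ITD bins
(2.965–3.902–4.839–5.776 mm) with half-open intervals and a closed last
bin, because the published bins share endpoints without a tie rule; values
outside the bins return an explicit `out_of_range`, never a silent NA.

## Surface extraction and areas

`label_to_mesh()` runs marching tetrahedra (six tetrahedra per cell around
the main diagonal, crack-free across cells) at level 0.5 on the binary eye
label. Binary data need care: the raw midpoint isosurface of a ball
overestimates its area by ~27% (the staircase never converges), so the
label is first passed through a small Gaussian filter in the *volume*
domain. The default `presmooth_sigma = 0.7` voxels leaves +2.2% on
spheres of any radius and −2.5% on a 50×40×45-voxel box; σ = 1.0 would be
better for spheres (+0.4%) but rounds sharp corners harder (−7% on small
boxes). No mesh-domain smoothing is applied anywhere — vertex relaxation
shrinks surfaces systematically and would bias the 2D-vs-3D comparison
that motivates the package.

Areas are always the triangle cross-product sum; region areas are the same
sum restricted to a face label, so the region areas add up to the total
exactly, by construction.

## Pose estimation and the overlay

The camera model is scaled orthographic: a stereomicroscope at long
working distance is near-telecentric, and a perspective pose cannot be
stably constrained by a handful of head landmarks. For non-coplanar
landmark sets the pose comes from the SVD factorization of the 2×3
least-squares projection matrix (nearest row-orthonormal matrix, mean
singular value as scale). For exactly three landmarks — which are always
coplanar — the out-of-plane components are completed algebraically, which
yields *two* reflection-related solutions with identical reprojection
error. The package resolves them with the eye-normal majority rule, plus a
landmark-near-side rule when the mesh is closed; but there is a genuine
degeneracy: the *sign of the in-plane tilt* of the landmark plane is
unobservable from three coplanar points, whatever the tie-break. For this
reason the phantom protocol includes one landmark off the ocelli plane (an
antenna base, a structure prominent in both photographs and CT volumes),
which makes the pose unique and well conditioned: with 0.5 px landmark
noise, rotation errors stay below 2° in ≥95% of trials. Poses whose RMS
landmark residual exceeds 5 px (configurable) are flagged, and
`project_mask()` refuses flagged poses unless overridden.

Annotation transfer labels a face as DRA iff it is front-facing, passes a
depth-buffer visibility test at its projected centroid, and its centroid
lands in a `TRUE` mask pixel. The depth tolerance is one median edge
length, scaled up for grazing faces (whose depth varies steeply across one
pixel). Faces straddling the mask boundary are decided by centroid
membership alone; their total area is reported as a boundary-uncertainty
attribute rather than silently absorbed. The reverse rendering
(`reproject_region()`) uses the same rasterizer, so the
render→project→reproject round trip measures only the labeling error:
face and pixel IoU are ≥0.95 on the default phantom (in practice ≈1.0).

## Emulating manual annotation

The study this workflow automates measured the DRA twice per specimen:
manual tracing of the photograph, and manual segmentation of the 3D model
using the mapped image as a reference. Two *independent* human boundary
judgments are therefore part of the measurement model, and the phantom
generator emulates them: `annotate_mask()` perturbs the exact rendered
mask boundary with a smooth periodic Gaussian process over the boundary
angle (harmonics 0–3, total sd 2 px — a realistic tracing error). The
equivalence cohort compares the 2D pipeline run on one annotation against
the 3D pipeline run on an independent annotation, which is what produces
mixed-sign paired differences. On the *exact* projections the comparison
is one-sided by theorem (a projection can never exceed the curved area),
and that inequality is checked separately and deterministically. Had the
signed-rank test been run on exact projections, n = 6 same-sign pairs
would force p = 2/2⁶ ≈ 0.031 regardless of how tiny the differences are —
a property of the test, not of the measurements.

## Virtual histology

Slices are sampled on a regular in-plane grid by trilinear interpolation;
out-of-volume samples are `NA`, never zero-filled, and a plane that misses
the volume is an error. Sample spacing may not exceed the voxel size.
Slice placement in the pipeline is a fan of planes through the eye center
about the DRA axis (the study protocol's seven slices per eye is a config
default, not a constant); planes through the center contain the radial
directions, which for a spherical eye are the local layer normals — so
thickness is measured along in-slice radial profiles without obliquity
correction.

Boundary detection on a profile: light 3-sample smoothing, gradient-magnitude
local maxima, merging of peaks closer than `min_separation`
(default 6 sample steps), then a plateau-amplitude guard — a boundary must
separate plateau medians by at least `min_contrast` (default 10%) of the
dynamic range. The plateau formulation matters: satellite gradient peaks
riding on a strong edge inherit the edge's amplitude under a window test
but carry no plateau difference of their own, and are dropped. Boundary
positions get parabolic sub-sample refinement. On oblique slices of the
volume phantom, lens/cone/rhabdom thicknesses are recovered well within
one voxel (typical errors 0.1–1 µm at 1.625 µm voxels). A manual
two-point mode (`measure_manual()`) mirrors interactive line tools for
parity with operator-driven measurements.

The rhabdom-continuity QC binarizes the slice to the rhabdom gray band,
fits a circle to the band (least squares), orders band pixels by arc
length and fails the slice iff any along-band gap exceeds the tolerance
(default twice the voxel size). A band specification that matches nothing
is a distinct QC *error*, not a fail. The check is monotone in the
tolerance by construction.

Eye regions operationalize "ommatidial rows" as geodesic distance over the
mesh in units of facet pitch, because individual facets are never
segmented: proximate = within 5 pitches of the DRA boundary, non-DRA =
beyond 20 pitches, and the rows in between get an explicit `buffer` label
— the study's own classes leave rows 6–20 unassigned, and the buffer makes
that explicit rather than guessing. "Vertically from the DRA" is read as
geodesic distance from the DRA boundary, not a screen-axis direction; this
is an assumption, recorded here. Distances are shortest paths on the
face-adjacency graph with centroid-to-centroid edge weights, which
overestimates true geodesics by up to ~20% on coarse meshes; the band
thresholds are far from the tested cases (3, 10, 25 rows), so the
classification is insensitive to this bias. Ommatidium thickness, where
needed, is taken as lens outer surface to rhabdom proximal boundary — the
sum of the three layer thicknesses — which is an assumption the source
protocol does not pin down.

## Statistics

Areas are linearized (√area, mm) before log transformation, so allometric
slopes are comparable to a linear body-size proxy. The allometric fit is
OLS of $\log\sqrt{A}$ on $\log \mathrm{ITD}$ with a two-sided t-test on
the slope at $n-2$ df; reduced major axis is available as an option for
allometry purists but OLS is the default, as it produces the conventional
t statistics. Note the calibration fact shown by simulation in the test
suite: the event $|\hat\beta - \beta| \le 2\,\widehat{SE}$ has exact
probability $P(|t_{18}| \le 2) = 0.939$ at n = 20, so "within 2 SE"
succeeds in ~94% of replicates in expectation, not 95%.

The paired signed-rank test drops zero differences (classical treatment,
count reported) and computes the exact two-sided p for ≤15 nonzero pairs
from the full distribution of $W^+$ over all $2^n$ sign assignments
(implemented as a convolution over midranks, mathematically identical to
enumeration and verified against a brute-force enumerator in the tests);
larger samples use the tie-corrected normal approximation, and both the
rank-sum statistic and the z value are always reported, since published
summaries differ in which one they print.

Region comparisons run a tie-corrected Kruskal–Wallis test across the
regions present, then pairwise Wilcoxon rank-sum tests with Holm
adjustment (configurable, including none — the source protocol names no
correction, and Holm is the conservative-safe default of standard
software). Group letters come from maximal cliques of the
not-significantly-different graph: matching letters mean no significant
difference. By default measurements are pooled to one mean per specimen ×
region before testing, reflecting the eye as the unit of replication;
because the specimen effect is shared across regions, the pooled test is
conservative under the null (simulated type-I error well below the nominal
0.05), which is the safe direction for claiming region contrasts.

## Numerical choices and degenerate inputs

* Isosurface level is fixed at 0.5 between binary labels — the symmetric
  choice.
* Empty annotation masks return area 0 with a warning; identical ITD
  points return 0 with a warning; empty regions reproject to an all-false
  raster with a warning. Nothing degenerate is silent.
* Collinear calibration points, collinear 3D landmarks, empty label
  volumes, planes that miss the volume, and band specs that match nothing
  are all hard errors with named causes.
* All generators are deterministic given a seed; child seeds are drawn
  below 2³¹. Fixture projects written twice with the same seed are
  byte-identical.
* Problem sizes used in the validation studies: 20480-face meshes,
  480²–560² px renderings, ~200³-voxel volume phantoms, 200-replicate pose
  and allometry studies, 500-replicate null calibration. These were chosen
  as the package's standard study conditions.

## Known limitations

* The sphere-cap eye has no facet lattice; facet pitch enters only as the
  row-to-distance conversion factor.
* Micro-CT at this resolution cannot resolve microvilli orientation, so
  DRA identity is established by the overlay (and, in the original wet-lab
  workflow, by TEM); the package's analogue of that validation is phantom
  ground-truth recovery, not biology.
* The scaled-orthographic model ignores perspective and lens distortion;
  at macro working distances this is appropriate, but close-up lenses with
  visible perspective would need a different camera model.
* Region banding by geodesic distance inherits the mesh's graph metric;
  on very coarse meshes the proximate band is biased narrow.
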