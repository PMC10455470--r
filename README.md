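# dramorph

Localization and morphometry of the insect **dorsal rim area (DRA)** in 2D
and 3D.

The DRA is the small dorsal patch of an insect compound eye that detects the
sky's polarization pattern. In bumblebees it is visible as a grey patch in
photographs, but invisible in micro-CT reconstructions of the same head.
`dramorph` implements an automated version of a combined 2D + 3D workflow:

* **2D planimetry** — calibrate the pixel scale from a grid paper glued to
  the head (similarity fit, residual reported), measure the planimetric DRA
  area from a binary annotation, measure the inter-tegular distance (ITD,
  the standard bee body-size proxy) and classify specimens into the study's
  size classes.
* **3D surface morphometry** — convert a binary eye-label volume into a
  triangulated surface (marching tetrahedra with a volume-domain
  anti-aliasing filter) and measure total and per-region surface areas by
  the triangle cross-product sum.
* **2D→3D registration** — estimate a scaled-orthographic camera pose from
  ocelli landmarks (orthographic factorization, least squares) and transfer
  the photo annotation onto the mesh by depth-buffered ray projection, so
  the DRA becomes a labeled region of the 3D surface; the round trip
  (reprojection) quantifies overlay fidelity.
* **Virtual histology** — extract arbitrary longitudinal slice planes from
  the volume by trilinear interpolation, run a rhabdom-continuity QC, and
  measure lens / crystalline-cone / rhabdom dimensions from gradient-based
  boundary detection along layer-normal profiles, tagged by eye region
  (DRA / proximate / buffer / non-DRA, defined as geodesic bands in units
  of facet pitch).
* **Statistics** — allometric log–log regression of linearized areas
  (`log √area = a + b·log ITD`, OLS with a slope t-test, RMA optional), an
  exact paired Wilcoxon signed-rank test (full sign enumeration for
  n ≤ 15, ties included), and Kruskal–Wallis + pairwise rank-sum region
  comparisons with Holm adjustment and compact-letter output.
* **Synthetic phantoms** — every stage is testable without any imaging
  data: sphere-cap eye phantoms with analytic areas, rendered views with
  known pose, layered volume phantoms with known thicknesses, annotation
  jitter emulating manual tracing, and allometric cohorts with a known
  power law.

The model at the core of the 2D/3D comparison: for a spherical cap of
angular radius θ, the true surface area is `2πR²(1−cos θ)` while its
planimetric projection is `πR²sin²θ`; their ratio `(1+cos θ)/2 → 1` as
θ → 0, which is why flat DRAs can be measured from photographs alone.

## Worked example

```r
library(dramorph)

# a phantom eye: R = 1.2 mm, DRA cap of 0.3 rad, 20480 faces
ph <- make_head_phantom(phantom_params())
ph
#> <phantom_truth> R = 1.2 mm, theta = 0.3 rad
#>   true DRA area: 0.404106 mm^2 of 18.0956 mm^2 eye

# recover the camera pose from the rendered ocelli landmarks
lms <- landmark_set(rbind(ph$params$ocelli_mm, ph$params$aux_landmarks_mm),
                    ph$landmark_px)
pose <- estimate_pose(lms, ph$mesh)
pose$residual_px
#> [1] 3.759839e-14

# transfer the photo annotation onto the mesh and measure in 3D
blank <- set_face_region(ph$mesh, seq_len(nrow(ph$mesh$faces)), "unlabeled")
lab <- project_mask(blank, pose, ph$rendered_mask)
region_area(lab, "DRA")
#> [1] 0.4051179

# compare with 2D planimetry through the same pixel scale
measure_area_2d(ph$rendered_mask, pixel_scale(1 / pose$scale_px_per_mm))
#> [1] 0.3963672

# allometry on a synthetic cohort (n = 20, true slope 0.8)
coh <- make_allometric_cohort(seed = 1)
fit <- fit_allometry(coh$itd_mm, coh$dra_area_mm2)
fit
#> <dra_allometry> log(sqrt(area)) ~ log(ITD), ols, n = 20
#>   slope 0.7500 (se 0.0636), t(18) = 11.7886, p = 6.714e-10, R^2 = 0.885
glance(fit)          # broom-style one-row summary
autoplot(fit)        # log-log scatter with the fitted power law
```

The 3D area (0.405 mm²) sits within 0.3% of the analytic cap area and
above the 2D planimetric area (0.396 mm²), whose deficit is the cos-factor
foreshortening of the curved cap — about 2% at θ = 0.3, vanishing for
flatter patches.

A complete synthetic project (six specimens, two per size class, with
photos, annotations, landmark files, gray volumes and label volumes) can
be written and processed end to end:

```r
manifest <- make_fixtures("project/", seed = 1)
report <- run_pipeline(manifest, pipeline_config(seed = 1))
report$specimens      # per-specimen areas, ITD, size class, QC
report$measurements   # tidy ommatidial measurement table
report$stats          # signed-rank, region comparison, allometric fits
```

A thin command-line wrapper is installed at `inst/cli/dramorph.R`
(subcommands `fixtures`, `run`, `stats`).

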