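---
title: "Quantifying entheseal changes on bone surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying entheseal changes on bone surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vera)
```

## The measurement problem

Muscle, tendon and ligament attachment sites on dry bone ("entheses" in
the anthropological shorthand) develop localized projecting surface
irregularities - entheseal changes - that are routinely used as proxies
for habitual mechanical loading in bioarchaeology, paleoanthropology and
zooarchaeology. Scoring them by eye is poorly repeatable; delineating the
whole supporting structure by hand is slow and demands long observer
training. This package implements a semi-automated alternative: the
operator supplies only a broad selection region (BSR) around the
structure of interest, and everything downstream - curvature estimation,
normalization, thresholding, artifact filtering and area measurement - is
deterministic code. Identical inputs and parameters give bit-identical
results, so the subjective surface of the method is reduced to one
auditable, replayable JSON selection file.

## The measurement chain

Given a triangle mesh of a bone in millimetres and a BSR:

1. **Cleaning** welds duplicate vertices (1e-6 mm), drops degenerate
   faces and unreferenced vertices.
2. **Optional smoothing** applies Taubin lambda/mu passes
   (lambda = 0.5, mu = -0.53, 3 passes by default). Taubin smoothing is a
   band-pass filter: it damps the edge-length-scale scanning artifacts it
   is meant for without the global shrinkage of plain Laplacian
   smoothing, so tubercle volume survives. *It is for scans that carry
   small sharp artifacts.* For models that are already smooth the correct
   setting is `smooth_enabled = FALSE`: smoothing an already-smooth noisy
   surface cannot change the rank order statistics that drive the
   segmentation (see below) - it only lengthens the spatial correlation
   of the noise, which makes noise blobs larger and harder for the
   artifact filter to remove.
3. **BSR isolation** subtracts any lesion masks from the BSR and extracts
   the submesh of faces whose three corners are all selected - the
   conservative rule, so no face area can leak in from outside the
   region.
4. **Minimum principal curvature** is estimated at every vertex by local
   quadric fitting: neighbours within a geodesic radius are expressed in
   the vertex tangent frame, a height patch
   $z = ax^2 + bxy + cy^2 + dx + ey$ is fitted by Gaussian-weighted least
   squares, and $k_{\min} \le k_{\max}$ are the eigenvalues of the shape
   operator of the patch. The sign convention is positive-convex:
   a projecting bump has $k_{\min} > 0$ at its apex, while ridge flanks
   and saddles go negative. The *minimum* curvature is the discriminating
   field: a point on a projecting irregularity is convex in every
   direction, so even its least-curved direction is positive, whereas
   ridges of the bone shaft at large are only convex transversally.
5. **Histogram equalization** replaces the field by its mid-rank quantile
   $(r - 0.5)/N$. This is the step that makes a fixed threshold mean the
   same thing on every specimen regardless of scanner, size or curvature
   scale. A constant field maps to 0.5 (neither selected nor maximally
   suppressed).
6. **Blue-band selection** keeps vertices with equalized value
   $\ge$ 0.75. The reference rendering maps the equalized field through a
   red-green-blue ramp and the operator selects the blue shades; on a
   linear ramp blue dominates green precisely above 3/4, so the blue band
   is the top quarter of the surface.
7. **Small-component removal** groups selected faces into edge-connected
   components and drops those whose bounding-box diagonal is below 2 mm
   (1 mm is the documented adaptation for small smooth models where the
   default removes everything). What survives is reported with per
   component and total 3D area in mm².
8. **Lesion flagging** runs in parallel: any above-threshold component
   whose diagonal exceeds 4 mm is flagged for operator review as a
   possible pathological or taphonomic lesion. Flags are never acted on
   automatically - exclusion is an explicit, documented operator decision
   recorded as a lesion-mask selection.

## Parameters and why their defaults are what they are

| parameter | default | units | rationale |
|---|---|---|---|
| `smooth_iterations` | 3 | passes | "slight" smoothing; enough to kill single-edge spikes |
| `neighborhood_radius` | 0.6 | mm | see below |
| `blue_threshold` | 0.75 | quantile | blue-dominant band of the RGB ramp |
| `min_component_diameter` | 2.0 | mm | artifact-removal threshold; 1.0 for small smooth models |
| `lesion_flag_diameter` | 4.0 | mm | lesion-exclusion guideline for entheseal analysis |

Two parameter choices deserve their full argument.

**The fit radius is physical (mm), not a multiple of the edge length.**
The equalized-field segmentation inherits the spatial correlation length
of the curvature estimate, which is set by the fitting support. If the
support is specified in edge lengths, the physical field changes whenever
the resolution does, and areas measured on resamplings of the *same*
surface disagree systematically. With a fixed 0.6 mm radius the
estimator sees the same physical patch at any resolution. The default
also keeps the correlation footprint (~1.2 mm diameter) safely below the
2 mm artifact threshold, so noise-driven selections remain removable -
if the footprint reached the threshold, noise and signal would become
inseparable *at any noise amplitude*, because rank equalization is
amplitude-invariant. Two further stabilizers serve the same
cross-resolution goal: samples are Gaussian-weighted (bandwidth = half
the radius), and each fit uses at most 24 distance-stratified samples so
its variance does not depend on how densely the patch is meshed.

**Component areas carry a midpoint rim correction.** Faces with exactly
two selected corners that border a retained component contribute half
their area. The true selection boundary runs mid-edge; counting only
fully-selected faces under-covers every component by a band one edge
wide, a bias proportional to mesh resolution that would otherwise
dominate comparisons across differently-meshed specimens. Component
membership, connectivity and diameters still use the strict face rule;
`core_area_mm2` preserves the uncorrected value.

## The synthetic phantom: what it emulates and what it does not

Real validation of this class of method used repeated measurements of
real bones; those scans cannot ship with a package. The phantom module
instead generates fully deterministic bone-like specimens with known
ground truth:

* a **capsule** (default: 20 mm shaft, 3.5 mm radius - a human proximal
  phalanx scale) or spheroid base;
* the base is built coarse, tangentially jittered and isotropically
  remeshed to the target edge length, because real scan triangulations
  carry no lattice regularity - a plain surface-of-revolution grid has
  curvature-fit errors correlated along its rings, a structure no
  scanner produces;
* Gaussian **bumps** $h\,e^{-d^2/2\sigma^2}$ of the geodesic distance to
  seeded surface positions stand in for entheseal changes; every vertex
  displaced by more than 5 % of the bump height is recorded as ground
  truth *before* noise is added (so the labeled footprint is a geodesic
  disc of radius $\sigma\sqrt{2\ln 20} \approx 2.45\sigma$);
* smooth seeded **noise** along the normals: white Gaussian displacement
  filtered once over the 1-ring with half the weight kept on the vertex,
  scaled to a 10 µm standard deviation - representative of a good
  structured-light scan at the recommended resolution. Because the
  segmentation is rank-based, the amplitude affects only the
  signal-to-noise ratio of weak bumps, not the behaviour of bump-free
  surfaces.

The **standard battery** mirrors a ten-specimen repeatability design:
bump counts cycle 0-4 (a zero-bump control is always present), heights
span 0.3-1.0 mm, widths 1.2-1.8 mm, bump centres stay far enough from
the shaft ends that every footprint lies fully inside the BSR, and two
mesh resolutions (0.18 / 0.20 mm) alternate - both within the
recommended acquisition band, because the protocol requires resolution
to be consistent across a sample. Battery phantoms are *already smooth*
by construction, so they are measured with `smooth_enabled = FALSE`, the
documented adaptation for such models.

What passing phantom tests shows: the chain detects sub-millimetre
projecting structure, rejects amplitude-free noise, respects the BSR,
and measures areas that agree across resamplings. What it cannot show:
performance on real cortical micro-texture, taphonomic surface damage,
or the operator variance of BSR delineation - those require real-scan
repeatability studies, which users should run on their own material
(the concordance correlation tooling in this package is there for
exactly that).

```{r battery, eval = FALSE}
batt <- standard_battery(10, seed = 1)
params <- segmentation_params(smooth_enabled = FALSE)
res <- run_vera(batt[[4]]$mesh, shaft_bsr(batt[[4]]$mesh), params)
res$total_area_mm2
```

## Validation statistics

The `stats` functions cover the analyses conventionally reported with
entheseal measurements: Lin's concordance correlation coefficient for
repeatability (population moments, the original estimator; 0.95 is the
conventional bar), paired *t* tests between repetitions, correlation PCA
(areas in mm² and covariates such as stride counts or body mass only
belong in one ordination after z-scoring), MANOVA with Pillai's trace
computed from the defining cross-product matrices
$V = \mathrm{tr}\,[H(H+E)^{-1}]$ with the standard F approximation,
OLS regression with $R^2$, ANCOVA with partial $\eta^2$ and a
homogeneity-of-slopes diagnostic, and Spearman screening against age and
body-size proxies. Spearman p-values are exact by enumeration up to
n = 8, deterministic Monte Carlo permutation (19 999 draws) below n = 30
- validation samples in this field are that small - and asymptotic
beyond. Assumption checks (residual normality, heteroscedasticity,
group dispersion) are emitted as a diagnostics table, never as gates.
No multiple-testing correction is applied by default; `stats::p.adjust`
composes when wanted.

## Numerical choices and degenerate inputs

* Equalization ties take mid-ranks; a constant field maps to 0.5.
* Rank-deficient quadric fits (collinear neighbourhoods) fall back to
  the discrete mean curvature for that vertex and are counted in a
  warning.
* Isolated vertices get zero curvature with a warning; boundary vertices
  use the $\pi$ angle-deficit convention and are pinned during smoothing
  and remeshing, so open fixtures keep their outline and a flat grid is
  a fixed point of the smoother.
* `resample_uniform` refuses targets below one tenth of the current
  median edge: refining further fabricates detail the scan never
  captured.
* Resolution below the 0.30 mm floor produces a prominent warning, not a
  hard stop - fossil scans may be irreplaceable, and the operator owns
  that trade-off.
* Meshes are fingerprinted (counts + coordinate hash) and every
  selection stores the fingerprint of its mesh; applying a selection to
  any other surface is a hard error.
* When segmentation returns zero components on a small smooth model, the
  result message points at the documented remedy (skip smoothing, 1 mm
  threshold) instead of silently switching parameters - any change must
  be applied consistently across a sample to keep measurements
  comparable.

## Known limitations

* The BSR itself is still an operator input; nothing here removes
  between-observer variance in drawing it, and per-enthesis selection
  recipes are data curation outside this package.
* Measured areas are comparable only at consistent acquisition
  resolution and parameters; the `params_digest` travels with every
  measurement record so mixed-parameter tables are detectable.
* Principal directions are not computed (only the two curvatures), and
  non-manifold edges are tolerated but not repaired.
* The sub-mm bumps of the phantom are idealized Gaussian mounds; real
  entheseal changes are irregular, and absolute detection thresholds
  (the ~0.5 mm height floor seen on phantoms) should not be read as a
  claim about real bone.

## Problem sizes

Package tests run the ten-phantom battery (~15-30 k vertices per mesh at
0.18-0.20 mm), plus two resamplings of each at 0.15 and 0.25 mm; a full
battery segmentation takes on the order of a second per specimen. Sphere
fixtures for the geometry oracles use subdivided icosahedra up to ~2.5 k
vertices. These sizes are chosen so the whole validation suite runs in a
few minutes on a laptop while each mesh is still dense enough (tens of
vertices per bump footprint) for curvature estimates to be meaningful.
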