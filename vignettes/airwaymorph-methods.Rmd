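---
title: "Measuring mandibular position and upper-airway change from surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mandibular position and upper-airway change from surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

After partial mandibular resection, the mandible is commonly reconstructed
with a fibula free flap. The graft rarely restores the original geometry
exactly: the condyles may end up in a slightly different pose, and the
neo-symphysis is often placed posterior to the native chin (a setback-like
position) because fibular bone is lower than the native mandibular body. From
orthognathic surgery it is known that mandibular setback narrows the upper
airway; the same concern applies to reconstructions. `airwaymorph`
quantifies, from paired pre- and post-operative surface meshes (STL exports
of CT segmentations), three things:

1. **Condylar pose change** — the rigid transform of each condyle between
   timepoints, reported as signed axis deviations (dX, dY, dZ), in-plane
   deviation magnitudes (dXY, dXZ, dYZ), the Euclidean deviation dXYZ, and
   rotations about the skull axes (Phi(X), Theta(Y), Psi(Z)).
2. **Symphyseal position change** — since the native symphysis and the
   fibular neo-symphysis differ in shape, positions are compared through the
   centre point S of each mesh's intersection with the midsagittal plane:
   S_dX (anterior positive), S_dZ (cranial positive), S_dXZ.
3. **Upper-airway change** — naso-, oro- and hypopharyngeal segment volumes
   between reference planes, percentage change post/pre, and
   cross-sectional-area (CSA) profiles sampled at 1 mm from the epiglottis
   plane (E-plane), with the minimum cross-sectional area (minCSA) per
   segment. A narrow minCSA is the quantity most relevant to obstruction
   risk.

All deviations are expressed in a skull-aligned frame: X anterior, Y
left-lateral, Z cranial, right-handed. The frame is built from an explicit
landmark configuration (`build_frame()`), because the interactive CAD
orientation step it replaces is not reproducible otherwise.

## Superimposition and pose fitting

Pre and post meshes are superimposed by rigid ICP restricted to a
user-specified mask of surgically unchanged cranial anatomy
(`register_icp()`); the surgical site must not influence the alignment.
Design choices:

* **Point-to-point ICP with Kabsch updates.** Correspondences are nearest
  vertices; each iteration solves the closed-form least-squares pose (SVD).
  On the phantom validation surface both point-to-point and point-to-plane
  converge to the exact pose; point-to-point was chosen because the update
  is closed-form and the implementation has no tuning parameters beyond the
  convergence rule (relative RMS change < 1e-8, at most 200 iterations,
  divergence flagged after 10 consecutive RMS increases).
* **Deterministic sampling.** Correspondence subsampling uses an
  evenly-spaced stride rather than a seeded RNG draw: results are identical
  across runs and independent of the caller's RNG state.
* **Principal-axes multi-start for region fits.** A condylar pose change of
  tens of degrees can put centroid-initialized ICP into a tangential-slide
  local minimum. `fit_region_transform()` therefore starts from the
  principal-axes (inertia) alignment of the two vertex sets in all four
  proper sign combinations plus the centroid init, and keeps the lowest-RMS
  solution. A final RMS above 0.5 mm raises a warning that the rigid-shape
  assumption (unchanged condyle) may be violated.

**Euler convention.** Rotations are decomposed as intrinsic X-Y-Z:
`R = Rx(phi) Ry(theta) Rz(psi)`, angles in degrees in (-180, 180]. At gimbal
lock (|theta| within 1e-6 degrees of 90) only the sum/difference of phi and
psi is determined; the tie-break sets phi = 0, folds the coupled angle into
psi and flags the output. Any fixed convention reproduces the method's
intent; this one is documented and regression-tested.

**Reference point.** The condylar translation components are the
displacement of the pre-operative condylar crop centroid under the fitted
transform. The original method used a CAD "reference object" whose exact
construction is not public; the crop centroid is the canonical rigid-body
surrogate and is stated in the output. Axis deviations are reported signed
(plane and Euclidean terms as magnitudes), since a posterior deviation must
carry its sign; absolute values are trivially derivable downstream.

**Symphysis centre point.** The centre is the *area centroid* of the
enclosed midsagittal section region (holes subtract, even-odd), not the
vertex mean — robust to non-uniform tessellation and to shape differences
between native and fibular bone. `s_dx` is post minus pre on the X axis, so
a setback is negative.

## Geometry kernel

No mesh-processing package is available in the target environment, so the
kernel is part of the package:

* **STL I/O**: binary and ASCII; vertices welded on a 1e-6 mm grid,
  degenerate faces (< 1e-12 mm^2) and duplicate facets dropped with counts
  reported. STL stores float32; everything downstream is double precision.
* **Volume**: signed-tetrahedron summation, gated on watertightness (every
  undirected edge shared by exactly two faces with opposite winding); the
  error message carries the boundary-edge count.
* **Sectioning**: triangle-plane crossings are keyed by the *mesh edge*
  that generated them, so chaining crossings into loops is exact — no
  coordinate tolerance is involved beyond the load-time weld. Vertices
  falling exactly on a plane are nudged to the positive side by 1e-12 mm in
  the signed-distance field only, which removes all degenerate cases
  (sections through vertex rings) without perturbing geometry.
* **Clipping**: half-space clip with triangle splitting; cut loops are
  capped by centroid fans, so clipped segments stay watertight and
  volume-valid. Fan capping is exact for star-shaped cut loops — true for
  all airway and phantom sections; strongly non-convex cut contours would
  need a general polygon triangulator, which is out of scope.
* **Areas and centroids**: shoelace formula in an orthonormal in-plane
  basis; multiple loops combine by even-odd winding (`"sum"`), so a lumen
  split around the epiglottis, or an annular section, is counted correctly;
  `"largest"` returns the maximal single loop.

## Airway conventions

The four reference planes (top of nasopharynx, naso/oro boundary, E-plane,
bottom of hypopharynx) are supplied by configuration as offsets along frame
Z with cranially oriented normals, validated to be strictly ordered. The
exact anatomical plane definitions belong to the segmentation protocol and
are deliberately configuration, not code.

* CSA planes are *parallel to the E-plane* ("at 1 mm intervals starting
  from the E-plane"), not locally orthogonal to a centerline.
* Sampling extent: the outermost offsets are the largest multiples of the
  spacing strictly inside the segment bounds (half-open at the far plane),
  so boundary planes are never double-counted between segments.
* Offset 0 (the E-plane itself) is book-kept with the hypopharynx; the
  oropharyngeal minimum also considers it. Both minima are reported with
  their offsets, making the convention auditable.
* An empty section at an interior offset is recorded as area 0 with a
  warning (possible collapsed lumen) rather than an error.

## Statistics

* **ICC(A,1)** (`icc_a1()`): two-way model, absolute agreement, single
  rating, from the mean squares
  `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
  McGraw-Wong F-based 95% CI. Perfect agreement collapses the interval to
  (1, 1); absent between-subject variance is flagged as degenerate. The
  test suite checks the estimate against mean squares obtained
  independently via `anova(aov(...))` to 1e-10.
* **One-tailed Spearman** (`spearman_one_tailed()`): midranks for ties; the
  one-tailed p is exact (full n! enumeration) for n <= 9 and uses the
  t-approximation `t = rho sqrt((n-2)/(1-rho^2))` above. The exact branch is
  validated against an independent enumeration oracle, the approximate
  branch against `cor.test`'s asymptotic p.
* **Descriptives** (`describe()`): median and quartiles by linear
  interpolation (type-7), the same rule throughout.
* The cohort layer runs a configuration-driven grid of one-tailed tests
  (anterior-posterior sources L_dX, R_dX, S_dX against airway outcomes).
  No multiplicity correction is applied by default — the analysis this
  reproduces applied none and discussed the type-I risk explicitly — but a
  Benjamini-Hochberg switch is available (`p_adjust = "BH"`).

## The synthetic world

Phantoms are schematic, not anatomical: a skull shell (ellipsoid plus an
asymmetry bump that anchors rotation recovery), condylar ellipsoids with a
symmetry-breaking bump (an ellipsoid alone is invariant under 180-degree
flips about its principal axes, which would make the pose unidentifiable),
a swept-arch symphysis crossing the midline, and an airway tube of
revolution with a controllable radius profile (constant 5 mm with a Gaussian
waist to 3 mm at offset -15 mm by default). Post-operative meshes are the
pre meshes with the stated per-region transforms applied; the skull is
unchanged. Fixed seeds give byte-identical STL files.

The cohort generator (`make_cohort()`) states its world once:

* setback `s_dx ~ Normal(-7.9, 5)` mm — posterior-dominant at the clinical
  scale (median magnitude near 8 mm), with `s_dz ~ Normal(0, 1.5)`;
* condylar motions with rotations `Normal(0, 2 deg)` and translations
  `Normal(0, 1.5 mm)` per axis — deviations of a couple of millimetres;
* the post-operative airway is the pre-operative tube scaled radially by
  `exp(g)`, `g ~ Normal(log sqrt(0.87), 0.15)`, so the median area and
  volume ratio is near 87%;
* `s_dx` and the airway response are coupled through a Gaussian copula with
  Pearson correlation `2 sin(pi rho_s / 6)` — the exact inversion of the
  Gaussian rank-correlation relation — corrected analytically for the
  independent nuisance noise (`nuisance_sd = 0.3`). An infeasible request
  errors with the attainable bound. This replaces a lookup-table
  calibration: the closed form is exact in population.

Cohort simulations use a coarser mesh resolution (64 circumferential
segments, 2 mm rings; single-case default 128 and 1 mm) to bound runtime;
the inscribed-polygon area deficit at 64 segments is about 0.16%, far below
the between-subject spread, and rank-based statistics are unaffected.
Cohort runs measure the stages the tested hypothesis needs (symphysis
sectioning and CSA profiles by default in `run_phantom_cohort()`); the full
chain including QC, superimposition and condylar fits is exercised by the
single-case tests.

**What a green test establishes — and what it does not.** The phantoms
validate the geometry and inference machinery: exact rigid recovery,
analytic volumes and areas, minCSA localization, correlation recovery at a
stated coupling, nominal type-I behaviour at coupling zero. They do not
emulate CT acquisition, segmentation artifacts, soft-tissue swelling,
posture-dependent airway shape, or anatomical shape variation, so clinical
reported values (median deviations, volume percentages, ICCs of repeated
human measurements) are outside what this package can reproduce without
patient data.

## Other decisions on points the protocol leaves open

* **Volume QC**: the stable-structure comparison is whole-mesh by default
  with tolerance 0.02 (2%), both configurable — neither the compared region
  nor the threshold is specified by the source protocol.
* **minCSA at boundaries**: whether the minimum search includes the
  boundary planes is unstated; here the E-plane is included (convention
  above) and the far planes are excluded by the half-open extent.
* **"Average ICC"**: `icc_table()` reports per-variable ICCs and their
  arithmetic mean, labelled as such; pooling across variables is not
  implied.

## Known limitations

* Fan capping assumes star-shaped cut loops (see above).
* Point-to-point ICP assumes sufficient shape anisotropy in the mask; a
  featureless (near-spherical) mask region cannot anchor rotation. Real
  crania and the phantom skull (with its bump) are fine.
* The exact permutation test enumerates n! orderings and is capped at
  n = 9 by default.
* Meshes are assumed rigid per region; condylar remodelling surfaces as a
  fit-RMS warning, not a measurement.
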