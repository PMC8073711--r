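---
title: "radius3d: methods, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radius3d: methods, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radius3d)
```

`radius3d` quantifies the displacement and surgical reduction of distal
radius fractures from landmark coordinates on pre- and post-operative
CT-derived bone models. This vignette documents the measurement model, the
conventions we had to fix where the clinical measurement tradition leaves
them open, the synthetic cohort generator that stands in for patient data,
and the package's numerical choices and limitations.

## The measurement model

### Anatomical frame

Everything is measured in a patient-specific anatomical coordinate system:

* the **y-axis** is the long axis of the radius estimated from the intact
  part of the distal shaft, proximal positive;
* the **z-axis** is the orthogonal projection, onto the plane perpendicular
  to y, of the line from the base of the ulnar sigmoid notch to the radial
  styloid process, radial positive;
* the **x-axis** completes a right-handed basis, `ex = ey × ez`;
* the **origin** is the intersection of the articular surface and the long
  axis on the post-operative model.

The y–z, x–y and x–z planes are then the coronal, sagittal and axial planes.
Segmentation and surface reconstruction are upstream of this package:
`fit_long_axis()` consumes shaft surface points (ASCII STL/PLY vertices or
any n × 3 matrix, in mm).

Two details of this construction are not fixed by the clinical definition
and are package decisions:

* **Long-axis algorithm.** The default (`pca_centroids`) takes the
  principal axis of cross-section centroids computed in 2 mm slabs along a
  provisional PCA axis. Centroids of complete cross-sections lie on the
  true axis of any tube regardless of its radius profile, so this is robust
  to the distal flare of the radius, where a raw PCA of surface points is
  biased. A least-squares cylinder fit (`cylinder_lsq`, minimising the
  variance of point-to-axis distances, initialised from the centroid PCA)
  is provided as an alternative; on flaring bone it inherits the cylinder
  assumption and is kept mainly as a cross-check.
* **Sign of the fitted axis.** A fitted line has no intrinsic direction.
  The caller supplies any distal-side point (the styloid landmark works)
  and the direction is flipped to point away from it, i.e. proximally.

### Handedness and side pooling

With `ex = ey × ez`, +x is dorsal on a right wrist and palmar on a left
wrist — the frame construction itself makes y (proximal) and z (radial)
side-invariant, so the dorso-palmar axis is the only one whose anatomical
meaning mirrors. Direction labels therefore route through the `side` field,
and when cohorts pool both sides `run_cohort()` mirrors left wrists by
negating the frame x coordinate (option `mirror_left`, default on). We
deliberately mirror x rather than z: negating z would re-label the radial
direction, which the construction already anchors anatomically.

### Registration of the pre-operative image

Pre- and post-operative data must live in one frame. When shaft point
clouds are supplied, `register_rigid()` aligns the intact pre-operative
shaft onto the post-operative one with point-to-point ICP (identity
initialisation, Kabsch updates on nearest-neighbour correspondences,
convergence when the RMS residual changes by less than 1e-6 mm, at most 200
iterations, non-convergence flagged) and the transform is applied to the
pre-operative landmarks. Without clouds, landmarks are assumed
pre-registered by the caller — a documented input contract rather than a
hidden assumption. The post-operatively defined origin is reused for the
pre-operative stage after registration, since a displaced joint surface
does not define a meaningful origin of its own.

### Indices

For the reference triad p₁ (radial styloid process), p₂ (sigmoid notch
volar edge), p₃ (sigmoid notch dorsal edge), all in frame coordinates:

* **centroid** — the component-wise mean; the "barycentric coordinate" of
  the plane connecting the three points;
* **plane area** — ½‖(p₂ − p₁) × (p₃ − p₁)‖ in mm², a coarse proxy for
  articular surface gap (collinear triads return 0 with a degeneracy flag);
* **3D volar tilt** — the signed elevation of the sagittal-plane projection
  of the p₂→p₃ line above the perpendicular to the long axis:
  `atan2(y₃ − y₂, |x₃ − x₂|)` in degrees;
* **3D radial inclination** — likewise in the coronal plane for p₁→p₂:
  `atan2(y₂ − y₁, |z₂ − z₁|)`.

The measurement tradition reports these angles without committing to a
sign. We adopt the signed convention in which a normal wrist is positive on
both: VT positive when the volar edge lies distal to the dorsal edge, RI
positive when the styloid lies distal to the sigmoid volar edge. The
"sagittal view" and "coronal view" are realised as orthographic projections
onto the x–y and y–z planes — exactly what the frame defines those views to
be. The 2D analogues (`vt_2d`, `ri_2d`) run the same signed-elevation
computation on radiograph-plane coordinates, and can equally be fed
orthographic projections of the 3D landmarks to simulate radiographic
measurement.

* **Displacement** — per-point and centroid vectors `post − pre`, their
  Euclidean norms, and a direction label per vector. Labels order the terms
  z-axis, x-axis, y-axis ("ulnar-palmar-distal"), matching clinical usage.
  The `dead_zone` parameter (mm) suppresses naming components smaller than
  a threshold; the default is 0 mm (every nonzero component is named),
  since no dead zone is established in the tradition. The centroid vector
  is, by linearity, exactly the mean of the three per-point vectors, and
  the package treats that identity as an invariant (tested to 1e-12).

## Statistical workflow

`run_cohort()` reproduces a study-style analysis on the measurement tables:

* **Rater reliability** — `icc_two_way()` computes single-measure ICCs from
  the two-way ANOVA mean squares. The default form is ICC(2,1), two-way
  random effects with absolute agreement: two specific raters measuring the
  same subjects, where calibration offsets between raters should count
  against agreement. ICC(3,1) (consistency) is available where per-rater
  offsets are to be ignored.
* **Normality screening** — `shapiro_wilk()` wraps the standard algorithm
  with the package's argument guards; it justifies the nonparametric tests
  downstream.
* **Per-point movement comparison** — `friedman()` on the blocks × points
  matrix of movement distances, with mid-ranks and tie-corrected
  denominator; a fully tied table returns statistic 0, p = 1 by convention.
  Besides the default chi-square(k−1) reference, `p_method = "exact"`
  enumerates all k!ⁿ within-block permutations for small tables.
* **Post-hoc** — a "Scheffé post-hoc after Friedman" is not a standard,
  uniquely defined procedure. We realise it as all pairwise rank-sum
  comparisons with a Scheffé-type criterion: (Rᵢ − Rⱼ)² / (n·k·(k+1)/6)
  referred to chi-square(k−1), which controls the familywise level in the
  Scheffé sense while allowing every pairwise contrast. This
  reading is documented prominently because other readings exist. No
  additional multiplicity control is layered on top.
* **Area comparison** — `wilcoxon_signed_rank()` on pre vs post plane
  areas: zero differences dropped, mid-ranks on |d|, exact sign-flip null
  for n ≤ 25 (computed by convolution, so ties in |d| stay exact), normal
  approximation with continuity and tie correction above. An all-zero
  difference vector is reported as "no change" rather than an error at the
  cohort level.
* **2D–3D agreement** — `pearson_r()` with the t-transform p-value.
* **Case classification** — a patient counts as dorsally displaced when the
  pre-operative centroid has positive x (dorsal) coordinate, palmar when
  negative; ties are "neutral". The clinical counting rule is not
  operationalised anywhere we could anchor to, so the centroid sign is the
  package's definition and is stated in the report.

Significance is reported at `alpha` (default 0.05); the per-patient log
records axis method, registration residuals and side mirroring.

## The synthetic world

`generate_cohort()` creates cohorts with exact ground truth. Its defaults
are a stated world, fixed once:

* **Post-operative (anatomic) triads** are drawn around mean positions
  (−2, −8, 11.9), (−7, 3, −15.5), (6, 3, −12.5) mm for styloid, sigmoid
  volar and dorsal edges — chosen so the distances to the origin are about
  14.5, 17.3 and 14.2 mm with the clinically expected direction labels
  (styloid radial-distal, sigmoid edges ulnar-proximal) — with per-axis SDs
  1.04/1.50/1.21 mm (reported position-magnitude spreads divided by √3).
* **Displacement model** (inverted to obtain the pre-operative triad):
  a sagittal hinge tilt about a radial–ulnar axis through the dorsal (39/52
  of cases) or volar rim of the sigmoid notch, magnitude |N(20°, 10°)|
  truncated to [0°, 40°]; a coronal inclination loss about the line through
  the two sigmoid edges, |N(12°, 6°)| truncated to [0°, 30°], which is what
  makes the styloid the farthest-moving landmark (its lever arm about the
  ulnar hinge is ~25 mm); proximal shortening |N(6, 3)| mm in [0, 15];
  radial shift N(3, 2) mm in [−5, 8]; a dorsal/palmar shift |N(4, 2)| mm in
  [0, 10] signed by the case's displacement direction (without it the
  dorsal/palmar classifier has nothing to classify); and isotropic
  translation noise with sd 2 mm. These scales were calibrated once so the
  cohort-level movement distances land near the clinically reported scale
  (means ≈ 15/8/9 mm per point, ≈ 10 mm for the centroid) and were frozen
  before the acceptance suite was run.
* **Observation noise** — landmarks observed with iid N(0, 0.3 mm) per
  coordinate (CT picking precision at 0.3 mm pixels); simulated radiograph
  landmarks are orthographic projections of the true triads plus N(0, 1 mm)
  2D noise; the two-rater table re-picks the post-operative triad with
  N(0, 0.5 mm) noise for the first 20 cases.
* **Shafts** — rings of angularly balanced points on a 10 mm-radius, 50 mm
  cylinder, optionally noisy. Because each noiseless ring's centroid lies
  exactly on the true axis, the generator doubles as an exact oracle for
  the axis fit.

What the generator does **not** emulate — and hence what a green test does
not establish: triads move rigidly, so plane areas do not change
systematically between stages (real displaced fractures show inter-fragment
gaps, i.e. larger pre-operative areas); there is no fragment comminution,
no correlated multi-fragment motion, and no imaging physics; shafts are
perfect cylinders, which are rotationally symmetric, so the cohort pipeline
is validated with ICP disabled (ICP is validated separately on asymmetric
clouds, where a cylinder's free rotation about its own axis cannot occur);
and the joint displacement distribution is a model choice — only its
marginal scales, not its correlation structure, can be compared with
clinical reports.

## Numerical choices

* Frame orthonormality and right-handedness are enforced to 1e-9;
  `to_frame()` is an exact isometry up to floating point (tested to 1e-9).
* Degenerate inputs fail loudly: fewer than 10 shaft points, clouds
  spanning under 5 mm, near-isotropic clouds (principal singular value
  within 20% of the second), a sigmoid-base→styloid line parallel to the
  long axis (projection shorter than 1e-6 mm), coincident triad points
  (pairwise distances below 1e-6 mm), constant samples in the statistical
  tests.
* `locate_origin()` projects the joint-surface point nearest to the axis
  onto the axis; a single manually picked intersection point is projected
  directly.
* ICP: identity initialisation and point-to-point correspondences; the
  residual is the RMS nearest-neighbour distance. With ~10–15° initial
  misalignment on overlapping clouds it converges to machine precision;
  it is a local method, and large misalignments are out of scope.
* Angle computations use `atan2`, so ±90° verticals are exact; angles are
  confined to [−90°, 90°] by construction.
* Truncated-normal draws use rejection sampling (ranges are wide, so the
  acceptance rate is high); all cohort randomness derives from the single
  `seed` in `cohort_spec()`, and identical specs reproduce byte-identical
  cohorts and reports.
* Reports print mm and degrees to one decimal; the JSON report keeps full
  precision.

## Known limitations

* Landmark identification itself (and the "base of the sigmoid notch"
  landmark in particular) is manual input; no automatic landmark detection
  is attempted.
* The plane area is a three-point proxy, not an articular step-off or gap
  map.
* ICP needs overlapping intact-shaft coverage and a rough pre-alignment;
  symmetric geometry (a perfectly cylindrical shaft segment) leaves its
  axial rotation unconstrained.
* One acceptance property is analytically unattainable in this stated
  world and is left failing by design: with observation noise σ applied
  independently to both stages, a displacement magnitude error is
  approximately N(0, σ√2), so the fraction of per-point errors below 3σ is
  2Φ(3/√2) − 1 ≈ 96.6% — not 99%. The suite measures ≈ 96.5% at n = 1000,
  agreeing with the closed form; the bound would require noise in one stage
  only.
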