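# radius3d

Landmark-based 3D morphometry of the distal radius: how far, and in which
anatomical direction, did the distal fragment of a fractured radius move
between the pre-operative and post-operative CT-derived bone models?

Distal radius fractures are the most common adult fracture, and the standard
radiographic indices used to judge displacement and surgical reduction —
volar tilt, radial inclination, shortening — are 2D projections with known
reliability problems. `radius3d` implements a computer-aided 3D alternative
for surgeons and skeletal-morphometry researchers: an anatomical coordinate
frame is built from the long axis of the intact shaft, three articular
reference points are tracked through surgery in that frame, and displacement
becomes a fully quantified 3D vector with a clinical direction label such as
`"ulnar-palmar-distal"`.

## The model

All coordinates live in an anatomical frame (units mm):

- **y-axis** — the long axis of the radius, fitted to the intact shaft
  surface (principal axis of 2 mm cross-section slab centroids, or a
  least-squares cylinder); proximal is positive.
- **z-axis** — the unit projection of the line from the base of the ulnar
  sigmoid notch to the radial styloid process onto the plane perpendicular
  to y; radial is positive.
- **x-axis** — `ex = ey × ez` (right-handed); dorsal is +x on a right wrist,
  and left wrists are mirrored into the same convention.
- **origin** — the intersection of the joint surface and the long axis on
  the post-operative image.

For the reference triad *p₁* (radial styloid), *p₂* (sigmoid notch volar
edge), *p₃* (sigmoid notch dorsal edge):

| index | definition |
|---|---|
| centroid (barycentre) | (p₁ + p₂ + p₃)/3 |
| plane area | ½ ‖(p₂ − p₁) × (p₃ − p₁)‖ (mm²) |
| 3D volar tilt | atan2(y₃ − y₂, \|x₃ − x₂\|) (°, palmar +) |
| 3D radial inclination | atan2(y₂ − y₁, \|z₂ − z₁\|) (°, styloid-distal +) |
| displacement | post − pre per point and centroid, with a direction label from the component signs |

The study-style statistical workflow is included: two-way ICC(2,1) for rater
agreement, Shapiro–Wilk screening, a Friedman test (tie-corrected, optional
exact permutation p) with a Scheffé-type post-hoc on the per-point movement
distances, Wilcoxon signed-rank for pre/post plane areas, and Pearson
correlation between the 3D angles and their 2D radiograph-plane analogues.
A synthetic cohort generator (`generate_cohort()`) provides exact ground
truth — hinge tilt, inclination loss, shortening, shifts, landmark noise —
so every stage is testable without patient data.

## Worked example

```r
library(radius3d)

spec   <- cohort_spec(n_patients = 52, seed = 11, lab_pose = FALSE)
cohort <- generate_cohort(spec)
dir    <- tempfile("cohort")
export_cohort(cohort, dir)

report <- run_cohort(run_config(
  landmarks = file.path(dir, "landmarks.csv"),
  raters    = file.path(dir, "raters.csv"),
  xray      = file.path(dir, "xray.csv"),
  seed = 1))
print(report)
```

```
Cohort report (n = 52 patients, alpha = 0.05)

Reference point positions (distance to origin):
  pre  styloid        19.9 +/- 2.8 mm  (radial-dorsal-proximal)
  pre  sigmoid_volar  14.8 +/- 4.0 mm  (ulnar-palmar-proximal)
  pre  sigmoid_dorsal 16.2 +/- 3.7 mm  (ulnar-dorsal-proximal)
  pre  centroid       8.9 +/- 3.3 mm  (ulnar-dorsal-proximal)
  post styloid        14.9 +/- 1.2 mm  (radial-palmar-distal)
  post sigmoid_volar  17.1 +/- 1.5 mm  (ulnar-palmar-proximal)
  post sigmoid_dorsal 14.3 +/- 1.2 mm  (ulnar-dorsal-proximal)
  post centroid       5.4 +/- 0.7 mm  (ulnar-palmar-distal)

Movement with reduction (post - pre):
  styloid        15.1 +/- 3.7 mm  (ulnar-palmar-distal)
  sigmoid_volar  8.3 +/- 2.7 mm  (ulnar-palmar-distal)
  sigmoid_dorsal 9.3 +/- 2.9 mm  (ulnar-palmar-distal)
  centroid       10.5 +/- 2.9 mm  (ulnar-palmar-distal)

Displacement direction counts: dorsal 39, palmar 13, neutral 0

Friedman test on movement distances: chi2 = 81.85, df = 2, p = 1.688e-18
Scheffe-type post-hoc:
  styloid vs sigmoid_volar: chi2 = 74.46, p = 6.775e-17  *
  styloid vs sigmoid_dorsal: chi2 = 44.46, p = 2.215e-10  *
  sigmoid_volar vs sigmoid_dorsal: chi2 = 3.85, p = 0.1462

Plane area pre vs post (Wilcoxon signed-rank): V = 602, p = 0.4308
Pearson 3D vs 2D VT: r = 0.93, p = 4.482e-45
Pearson 3D vs 2D RI: r = 0.94, p = 6.601e-51
ICC(2,1) VT (two raters): 0.92
ICC(2,1) RI (two raters): 0.83
```

Reading it: each reference point's movement with reduction is a mean ± SD
distance plus the modal direction label; the radial styloid moves
significantly farther than either sigmoid-notch edge (Friedman + post-hoc,
here p < 0.01), the fragment population is predominantly dorsally displaced
(39 vs 13, classified by the sign of the pre-operative centroid's x
coordinate), and simulated 2D radiograph measurements correlate strongly
with their 3D counterparts.

A command-line wrapper with `simulate`, `measure`, `cohort`, `stats` and
`validate` subcommands is installed at `inst/cli/radius3d`:

```sh
Rscript inst/cli/radius3d simulate --out /tmp/demo --n 10 --frame-coords
Rscript inst/cli/radius3d cohort --landmarks /tmp/demo/landmarks.csv --out /tmp/demo_report
```

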