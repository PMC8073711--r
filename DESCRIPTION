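Package: radius3d
Title: Three-Dimensional Assessment of Distal Radius Fracture Displacement and Reduction
Version: 0.1.0
Authors@R:
    person("radius3d", "developers", email = "radius3d@example.org", role = c("aut", "cre"))
Description: Landmark-based three-dimensional morphometry of the distal radius
    for quantifying fracture displacement and surgical reduction. Builds an
    anatomical coordinate frame from the long axis of the intact radius shaft
    and the sigmoid-notch/styloid landmarks, expresses pre- and post-operative
    reference-point triads (radial styloid process, sigmoid notch volar and
    dorsal edges) in that frame, and derives per-point and centroid
    displacement vectors with anatomical direction labels, triangle plane
    areas, and 3D volar tilt and radial inclination angles, together with
    their 2D radiograph-plane counterparts. Includes the accompanying
    statistical workflow (two-way intraclass correlation, Shapiro-Wilk
    screening, Friedman test with a Scheffe-type post-hoc, Wilcoxon
    signed-rank, Pearson correlation), a synthetic-cohort generator with exact
    ground truth for validation, rigid iterative-closest-point registration,
    ASCII STL/PLY point ingestion, and a command-line interface producing
    cohort reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
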