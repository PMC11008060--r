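Package: airwaymorph
Title: Three-Dimensional Mandibular Position and Upper-Airway Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies positional change of the reconstructed mandible
    (condyles and symphysis) and the associated change in upper-airway
    geometry from paired pre- and post-operative surface meshes. Provides
    STL input/output, watertight-mesh volumetry, plane sectioning and
    clipping, rigid iterative-closest-point superimposition on unchanged
    cranial anatomy, a skull-aligned anatomical coordinate frame, condylar
    displacement and rotation metrics, symphysis centre-point deviations in
    the midsagittal plane, pharyngeal segment volumes and 1 mm
    cross-sectional-area profiles with minimum cross-sectional area
    detection, intraclass correlation reliability, one-tailed Spearman
    correlation, and a synthetic phantom generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
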