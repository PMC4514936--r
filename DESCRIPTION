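Package: splintaccuracy
Title: Fiducial-Based Accuracy Analysis of CAD/CAM-Planned Maxillary Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how accurately a virtually planned Le Fort I maxillary
    repositioning was executed, starting from 3D coordinates of nine fiducial
    bone screws (three each in skull, maxilla and mandible) measured at the
    planned and post-operative timepoints. Computes per-region rigid pose
    differences (barycenter translation plus pitch/roll/yaw from a Kabsch
    least-squares rotation), root-mean-square-deviation accuracy statistics,
    Bland-Altman limits of agreement with confidence intervals, and the
    decomposition of maxillary repositioning error into mandibular (condylar)
    error plus intrinsic splint error. Includes a seeded synthetic-specimen
    generator with known ground truth, landmark CSV/JSON input-output, and a
    consistency check linking limits-of-agreement tables to RMSD tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
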