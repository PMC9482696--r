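Package: romsfp
Title: Joint Range of Motion Analysis with Spherical Frame Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rotational joint range of motion (RoM) from bone
    landmarks and motion-capture pose data. Builds anatomical coordinate
    systems from geometric-primitive fits to landmark point sets, recovers
    rigid poses from marker clouds, decomposes relative joint rotation with
    the Z-Y-X (flexion/extension, abduction/adduction, long-axis rotation)
    Euler convention, projects pose space onto the unit sphere (spherical
    frame projections), summarises per-axis extremes with their concomitant
    rotations, and compares in vivo stride data against pooled ex vivo
    pose-space regions. Includes simulators for torque-thresholded ex vivo
    sweep protocols and in vivo stride cycles so the full pipeline runs on
    synthetic joints with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
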