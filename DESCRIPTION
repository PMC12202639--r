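Package: ergoseat
Title: Seat-Comfort Biomechanics: Pressure-Map Metrics, Spinal Angles,
    Shape Averaging, Mesh Morphing and Foam Hysteresis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis toolkit for human-seat static comfort studies.
    Computes seat pressure distribution (SPD) uniformity and related
    body-pressure-map statistics (maximum/average pressure, contact
    area, 4-kPa pressure binning, hip/legs and waist/back region
    segmentation, ideal-range comfort classification); Cobb-style
    sagittal spinal angles (cervical lordosis, thoracic kyphosis,
    lumbar lordosis) from vertebral endplate landmarks; generalized
    Procrustes mean-shape construction for body-surface point clouds
    with radial-basis-function landmark correspondence; thin-plate
    spline landmark-driven mesh morphing; a hysteretic foam
    constitutive point model with least-squares identification of the
    unloading parameters; and comparison machinery (percent deviation,
    histogram distance, rank-correlation trend similarity) for
    simulation-versus-experiment and surface-versus-internal analyses.
    A seeded synthetic-data generator emulates pressure-mat exports,
    sagittal spines with prescribed curvature, families of body scans
    around a known mean shape, and foam load-unload tests, so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
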