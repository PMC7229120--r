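Package: splitscope
Title: Trajectory-Dependent and Place Coding Analysis for Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for one-photon hippocampal calcium imaging
    recorded during continuous spatial alternation on a figure-8 maze.
    Classifies trajectory-dependent ("splitter") neurons on the maze stem
    with a trial-label permutation test, place cells with a spatial mutual
    information shuffle test, decodes upcoming turn direction from
    population stem activity with a linear discriminant, registers neurons
    across sessions from ROI centroids, quantifies class-dependent
    cell turnover and spatial stability across days, and tracks the onset
    (ontogeny) of trajectory-dependent versus spatial coding. Includes a
    seeded synthetic-data generator with known ground-truth coding labels
    so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
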