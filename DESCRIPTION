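Package: hertzmap
Title: Hertzian Analysis of AFM Force Curves and Tissue Stiffness Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) indentation
    measurements on soft tissue with spherical (colloidal-bead) probes.
    Converts raw force-displacement records into force-indentation curves
    (baseline correction, contact-point detection, deflection correction),
    estimates the apparent elastic modulus with the Hertz model for a
    sphere on an elastic half space, applies contact-mechanics validity
    checks and linearity-based curve quality control, assembles per-cell
    moduli into grid stiffness maps with explicit failed-measurement
    markers, and aggregates and compares groups with the nonparametric
    workflow standard in tissue biomechanics (per-sample medians,
    per-tissue mean of medians, D'Agostino-Pearson normality screen,
    Mann-Whitney, Wilcoxon signed-rank, Kruskal-Wallis with Dunn's
    post-hoc, and a dilution-series regression for hydrogel standards).
    Includes a synthetic force-curve generator with known ground truth
    (implicit cantilever-deflection coupling, thermal-noise deflection
    series for spring-constant calibration, heterogeneous stiffness
    fields) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, withr, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'calibration.R'
    'processing.R'
    'hertz.R'
    'mapping.R'
    'stats.R'
    'io.R'
    'pipeline.R'
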