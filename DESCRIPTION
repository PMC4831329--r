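Package: lungsim
Title: Forced-Oscillation Impedance Simulation of Airway Trees with
    Ventilation-Defect Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates respiratory-system resistance and reactance measured
    by the forced oscillation technique on an asymmetric, morphometry-matched
    airway-tree model in which airways spatially coincident with ventilation
    defects are narrowed. Provides a 26-generation stochastic airway-tree
    generator, Womersley (oscillatory-flow) branch impedances combined by a
    lumped-element network from 0.2 to 32 Hz, ventilation-image K-means
    cluster mapping and ventilation defect percent (VDP), seeded
    region-growing thoracic-cavity segmentation, fiducial-based rigid
    coregistration of the tree model to image space, defect-driven airway
    closure at selectable generations, a synthetic phantom and cohort
    generator, and the statistical layer (correlations, Fisher z comparison,
    ANCOVA slope tests, Holm-Bonferroni correction) used to relate VDP to
    impedance predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
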