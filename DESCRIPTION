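Package: sucsim
Title: Finite-Element Simulation of Subdural Cortical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volume-conductor modelling of subdural cortical stimulation
    (SuCS) on a parametric extruded-slab model of the precentral gyrus.
    Builds labeled tetrahedral meshes with subdural disc electrodes and a
    five-contact paddle array, assigns isotropic or anisotropic white-matter
    conductivity tensors (volume-constraint normalization or fixed-ratio
    models) from synthetic fiber fields, solves the quasi-static Laplace
    equation with a first-order finite-element method, and computes
    stimulation metrics: effective volume and penetration depth against a
    motor current-density threshold, impedance, and voltage/current sweep
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xml2,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
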