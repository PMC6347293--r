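Package: tipwall
Title: Cell Wall Biomechanics of Brown-Algal Tip Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse and simulate tip growth of walled cells whose
    morphogenesis is controlled by a gradient in cell wall thickness rather
    than by graded wall mechanical properties. The package turns traced cell
    contours into averaged meridional profiles with principal curvatures,
    corrects transmission electron microscopy wall-thickness measurements for
    off-meridian sectioning and fits thickness-gradient models, estimates
    turgor from incipient-plasmolysis assays, computes axisymmetric thin-shell
    wall stresses and the expected viscoplastic strain rate under self-similar
    growth, infers Lockhart parameters (extensibility and yield threshold),
    forward-simulates viscoplastic tip growth with parameter optimisation,
    derives the wall-material deposition flux that maintains the thickness
    gradient, and provides bootstrap robustness analyses, bead-trajectory
    orthogonality statistics and FRAP recovery fitting. A synthetic-data
    module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
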