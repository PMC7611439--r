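Package: symperc
Title: Planar Reflection Symmetry, Perceptual Dissimilarity Models and
    Symmetry-Augmented Classification
Version: 0.1.0
Authors@R: person("symperc", "maintainers", email = "symperc@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing object representations with human visual
    perception and for improving linear classifiers with planar
    reflection-symmetry features.  Provides a part-composable synthetic
    stimulus generator (two-part objects, Gabor banks, simulated
    dissimilarity tables), pixel-based strength-of-symmetry scoring about
    arbitrary in-plane axes, weighted principal-component distance models
    of perceptual dissimilarity with split-half reliability correction,
    residual diagnostics (symmetry and area-ratio covariates, shared-part
    binning, metric multidimensional scaling), a late-fusion pipeline that
    stacks a linear classifier on base and symmetry posteriors, and
    network-unit probing (ablation importance, symmetry modulation index
    with bootstrap, Gabor spatial-frequency modulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
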