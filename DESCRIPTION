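Package: jet2r
Title: Protein-Protein Interface Prediction from Single Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction sites on the surface of a
    single protein structure by combining evolutionary conservation, amino-acid
    interface propensities and the circular-variance descriptor of local
    surface geometry. Implements three scoring schemes with automated scheme
    selection, a seed / extension / outer-layer patch-growing algorithm, an
    iterative consensus mode, an internal Shrake-Rupley solvent-accessibility
    calculation, and evaluation machinery based on the support / core / rim
    decomposition of experimental interfaces. Synthetic protein-like fixtures
    with planted ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
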