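Package: augvol
Title: Semiautomatic Volumetry of Bone Augmentation from Intraoral Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the volume added between a baseline intraoral surface scan
    and one or more post-augmentation scans of the same anatomy. Implements STL
    reading and validation, coarse three-point alignment followed by weighted
    iterative-closest-point refinement (Kabsch), trimming and solidification of
    open surface patches, dual region-of-interest Boolean subtraction on a
    robust voxel lattice, divergence-theorem and slice-based volume computation,
    and the accompanying statistical layer (paired TOST equivalence tests,
    two-way mixed-effects single-measure intraclass correlation, Wilcoxon
    signed-rank). A synthetic ridge phantom generator with analytically known
    added volume makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
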