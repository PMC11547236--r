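Package: bounti
Title: Boundary-Preserving Threshold Iteration for Multi-Part Hard-Tissue Segmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of multi-part hard-tissue structures
    (e.g. the bones of a craniofacial skeleton) in 3D grey-value volumes
    such as micro-CT scans. A seed segmentation of disarticulated
    components is extracted at a high initial threshold and grown through
    a descending schedule of thresholds down to a low target threshold,
    so that the separation achievable at the high threshold is preserved
    while the bone definition of the low threshold is reached. Includes
    16-bit TIFF stack input/output with bit-depth conversion rules,
    manual-seed modes, a synthetic phantom generator with ground truth,
    per-segment Dice scoring, parameter-sensitivity sweeps, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, Segmentation, Visualization
RoxygenNote: 7.3.3
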