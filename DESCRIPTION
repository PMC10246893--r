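Package: phenoshape
Title: Spatially Resolved Immune Phenotyping of Segmented Tissue Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated cell-type annotation of segmented single-cell
    statistics from multiplexed tissue imaging, using binary phenotype
    attribution matrices dynamically rescaled to each sample and Spearman
    rank correlation; kernel-density activation-status thresholding;
    detection of inflammatory cell clusters as disjoint alpha-shape
    polygons built from a Delaunay triangulation with circumradius
    filtering; and cell-to-structure distances to an alpha-shape epidermis
    model through a k-d tree nearest-neighbour index. Includes a rule-based
    histo-cytometry gating oracle for accuracy validation, a synthetic
    single-cell sample generator with ground truth, sample-level
    quantification (densities per cubic millimetre, cluster composition,
    distance summaries) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
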