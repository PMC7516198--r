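Package: scratchTopo
Title: Single-Cell Detection and Tissue Topology Metrics for Scratch Wound Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Detects single cells in scratch-wound (wound-healing) assay
        microscopy from dot annotations using a belief-map-regressing U-Net,
        segments the wound region from the detected coordinates, and derives
        topological metrics of the cell monolayer: Voronoi polygon-class
        distributions, polygon co-occurrence statistics against a
        random-mixing baseline, local cell density (LCD) at configurable
        neighbour ranks, wound-distance-normalised LCD, and a per-well
        fold-change signature projected by principal component analysis.
        Includes a synthetic monolayer generator with known ground-truth cell
        centres for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, Rcpp, EBImage, e1071,
        jsonlite, yaml, tiff, png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
biocViews: CellBiology, Software, SingleCell, Segmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
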