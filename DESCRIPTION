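Package: ZipperQuant
Title: Quantitative Microscopy of Filopodia Zippering, Cell Motility and
    Omics Bookkeeping
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cell-cell contact "zippering" in adherent cancer
    cells from fluorescence microscopy and integrates the matching omics
    bookkeeping. Counts intensity peaks (filopodial contacts) along
    constant-distance cell-cell profiles and per-cell perimeter contours,
    computes contact and filopodia densities per unit length, bins density
    against cell-cell distance with Freedman-Diaconis widths, measures
    distance-to-first-neighbor distributions from binarized fields, computes
    ensemble mean-squared displacement and explored area from wound-healing
    trajectories, estimates filament persistence length from Fourier
    tangent-angle modes (inverse-square-law fit of the ensemble mode
    variance), and performs fold-change threshold subsetting, set overlap and
    typed interaction-network filtering for proteome-transcriptome
    integration. A ground-truthed synthetic-data generator (two-cell contact
    scenes, Brownian and persistent random walks, worm-like-chain filament
    ensembles, Poisson point patterns, differential-expression tables) makes
    every stage verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Software, Network, Proteomics
RoxygenNote: 7.3.3
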