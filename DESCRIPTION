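Package: densiligand
Title: Ligand Identification from 3D Density-Map Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for recognizing small-molecule ligands in
    fragments of experimental 3D density maps. Covers reading and writing
    MRC/CCP4 voxel maps, sigma-level thresholding of crystallographic
    difference maps, a three-step normalization procedure for cryoEM Coulomb
    potential maps (zero-inflation reduction, quantile thresholding,
    resolution-keyed voxel rescaling), connected-component blob extraction
    with quality filters, four point-cloud sampling strategies, a sparse
    3D-convolution classifier with channel attention and NetVLAD descriptor
    aggregation, ligand-group assignment via molecular-graph signatures,
    grouped stratified evaluation protocols, and a synthetic density-blob
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
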