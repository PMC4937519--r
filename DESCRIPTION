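Package: xlwalk
Title: Solvent Accessible Surface Distances and Crosslink-Based Scoring of Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes solvent accessible surface distances (SASD) between
    lysines and chain N-termini of a protein structure on a voxel grid, and
    scores candidate structural models against crosslinking mass spectrometry
    data. Implements the matched/non-accessible crosslink score (MNXL) with a
    normal-density reward for satisfied crosslinks and flat penalties for
    violating and non-accessible ones, alongside the classical number of
    violations (NoV) and sum of violation distances (SoVD), in SASD or
    Euclidean distance modes. Includes evaluation utilities (Calpha-RMSD,
    Pearson correlation, top-k precision with tie resampling, bootstrap
    crosslink-recovery curves, distance-cutoff scans), a synthetic structure
    generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
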