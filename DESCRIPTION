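Package: lungtda
Title: Topological Radiomics for Airway Trees in Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Persistent-homology radiomics for branching airway structures
    segmented from chest CT. Computes directional (upwards) complexity from
    degree-0 sublevel-set persistence of a height function on centerline
    trees, bronchial-tree length and branch-point counts, branch-to-branch
    proximity from degree-1 alpha-complex persistence on centerline nodes,
    and degree-2 void barcodes from lobe/airway surface voxels. Barcodes are
    compared with bottleneck and Wasserstein distances, embedded in 2D by
    classical multidimensional scaling, and summarised with pairwise
    Kolmogorov-Smirnov group statistics. Includes seeded generators for
    synthetic airway trees, voxel phantoms and multi-group cohorts so the
    whole pipeline is exercisable without patient data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    clue,
    RNifti,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
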