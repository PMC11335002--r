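Package: vertbend
Title: Digital Bending Experiments on Vertebral Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds articulated intervertebral joint models from triangulated
    vertebral meshes and estimates per-joint range of motion (ROM) in six
    bending directions by incremental rotation sweeps under bony-intersection
    and soft-tissue strain constraints, across a factorial uncertainty grid of
    joint spacing, intersection threshold and strain allowance. Includes
    relative joint stiffness estimation from lever arms and centrum dimensions,
    structure-removal experiments (neural-spine truncation, intercentrum
    inclusion/removal), post-processing of ROM into ternary mobility
    proportions and craniocaudal profiles, residual-randomization permutation
    MANOVA for functional comparisons, and a parametric synthetic vertebra
    generator so the whole pipeline is testable without CT scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
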