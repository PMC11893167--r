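Package: ribomesh
Title: Membrane-Contextual Morphometrics of Mitochondria-Associated
    Ribosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric analysis of cytoplasmic ribosomes in the context of
    triangulated mitochondrial membrane meshes, as measured by cryo-electron
    tomography and subtomogram averaging. Classifies ribosomes as
    import-oriented from the distance between the peptide exit tunnel and the
    outer mitochondrial membrane (OMM), quantifies their spatial clustering
    with Ripley's K against a surface-constrained null, builds and randomizes
    ribosome-associated OMM patches, scores their overlap with
    crista-associated OMM, maps local OMM-IMM distances, and detects putative
    polysome chains from mRNA entry/exit site adjacency. Includes a synthetic
    scene generator (nested membrane meshes with crista-junction wells and
    particle decorations with known ground truth) so the whole pipeline is
    testable without tomography data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
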