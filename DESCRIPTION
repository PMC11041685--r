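Package: hexfract
Title: Hierarchical Assembly Geometry and Fractal Analysis for Self-Assembling Protein Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of hierarchical, fractal
    self-assembly of oligomeric enzymes built from hexameric rings of dimers.
    Generates coarse-grained Sierpinski-order and compact triangular
    assemblies, enumerates dimer-dimer fractal contacts and realizes maximal
    bond sets under interface-passivation rules, scans polyhex layouts for
    minimal interface frustration, estimates box-counting (Hausdorff)
    dimensions of silhouette images, computes rigid-body geometry (dihedrals,
    rotations, triangle-closure gaps), radius of gyration and Debye/Guinier
    small-angle scattering analysis, solves a concentration-, pH- and
    ligand-coupled mass-action oligomer equilibrium, and quantifies oligomeric
    state populations from single-particle mass-photometry events. Includes
    seeded synthetic-data generators for mass events, scattering profiles and
    degraded silhouette images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    withr,
    bio3d,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
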