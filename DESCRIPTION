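Package: tmdpath
Title: Targeted Molecular Dynamics Pathways for Two-State Proteins at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses conformational transitions between two
    known end-state structures of a protein using a coarse-grained dual-basin
    structure-based model driven by a targeted molecular dynamics (TMD)
    restraint on the mass-weighted RMSD to the target. Includes PDB and
    multi-model PDB trajectory input/output, Kabsch superposition with
    analytic RMSD gradients, Langevin (BAOAB) dynamics with staged
    minimization and heating protocols, dynamical cross-correlation matrices,
    hydrogen-bond occupancy and hydrophobic-contact analysis, segment
    mass-center distance series, grid-based pocket and cavity volume
    measurement, correlated-segment network construction, and synthetic
    two-state toy systems with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
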