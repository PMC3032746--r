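Package: fmoscore
Title: Quantum-Chemical Fragment Interaction Scoring of Protein-Ligand
    Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregates fragment molecular orbital (FMO) pair interaction
    energies into a gas-phase binding enthalpy, combines it with
    Poisson-Boltzmann polar solvation (supplied as input), a solvent
    accessible surface area (SASA) derived nonpolar solvation term and a
    rotatable-bond conformational entropy penalty, and fits a NIPALS
    partial least squares (PLS) model that rescales the four physical
    terms into predicted binding free energies. Ships the 28-compound
    CDK2 inhibitor reference set, a parser for FMO program output,
    a deterministic Shrake-Rupley SASA implementation, IFIE map
    construction, grouped cross-validation statistics (r2, q2, RMSEE,
    RMSEP) and synthetic-data generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
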