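Package: qmflip
Title: Histidine Protonation Assignment by Quantum-Mechanical Flipping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns the protonation state of histidine imidazole rings in
    macromolecular models. Around a target histidine a small quantum-chemistry
    cluster is excised (all entities within a buffer distance, severed peptide
    bonds capped with hydrogens, environment heavy atoms frozen), the six
    protonation/ring-flip configurations are enumerated and geometry-minimized
    with a planar torsion restraint, and their energies are compared after a
    proton-count correction derived from a linear pKa calibration of
    semi-empirical heats of formation. Ships the 20-solute calibration table,
    a MOPAC input/output adapter, a deterministic surrogate energy backend so
    the full pipeline runs without a QM engine, hydrogen-bond / RMSD / rotamer
    scoring, and a synthetic micro-environment generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'qmflip-package.R'
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structure-io.R'
    'cluster-builder.R'
    'his-config.R'
    'surrogate.R'
    'qm-backend.R'
    'calibration.R'
    'metrics.R'
    'decision.R'
    'fixtures.R'
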