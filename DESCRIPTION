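Package: comfa
Title: Comparative Molecular Field Analysis (3D-QSAR) with Docking-Based Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, tested implementation of the CoMFA 3D-QSAR workflow for
    receptor-docked ligand series: selection of docking poses by the
    salt-bridge criterion to a conserved anchor residue, Gasteiger (PEOE) and
    Gasteiger-Hueckel point charges, probe-based steric (Lennard-Jones) and
    electrostatic molecular interaction fields on a regular lattice, partial
    least squares (NIPALS) regression of pIC50 on the fields with leave-one-out
    cross-validation and optimal-component selection, progressive-scrambling
    stability analysis, and STDEV*COEFF contour-map export in OpenDX format.
    Includes a synthetic aligned-ligand generator with a planted sparse
    field-to-activity model so the whole pipeline can be exercised and
    validated without proprietary modelling software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
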