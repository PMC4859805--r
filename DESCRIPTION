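Package: hubkit
Title: Quantitative Models of CaMKII Hub Assembly and Subunit Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium models and estimators for studying the oligomeric hub
    of Ca2+/calmodulin-dependent protein kinase II (CaMKII) and its
    activation-triggered subunit exchange. Implements direct and competition
    fluorescence-polarization binding models with nonlinear least-squares
    dissociation-constant fitting, model-implied IC50 and tethered-ligand
    effective concentration; charge-state inference and mass deconvolution of
    native electrospray spectra with oligomer and tag stoichiometry assignment;
    a combinatorial model of subunit exchange through monomer or dimer units
    with likelihood-based exchange-unit inference and a stochastic swap
    simulator; FRET donor/acceptor ratio time courses; and Calpha-level
    structural analysis (Kabsch superposition, displacement fields, screw-axis
    ring and spiral geometry, elastic-network normal modes, interface polar
    contacts). Seeded synthetic-data generators emulate every input so the
    full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
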