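Package: tmcSMILES
Title: SMILES Generation for Mononuclear Transition Metal Complexes from
    Cartesian Coordinates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts xyz geometries of mononuclear transition metal
    complexes (TMCs) plus an overall charge into canonical SMILES with
    dative metal-ligand bonds and explicit metal oxidation states. Bond
    connectivity is perceived from interatomic distances with covalent
    radii, ligand charges are assigned by counting doubly occupied
    extended Hueckel molecular orbitals with iterative frontier-orbital
    corrections, ligand Lewis structures are found by valence
    enumeration with resonance-form scoring (largest aromatic system,
    fewest non-coordinating formal charges, carbene preference), and the
    complex is reassembled with ligand-to-metal dative bonds. Also
    provides a repair procedure for raw CSD-style SMILES with covalent
    metal bonds, a three-level SMILES agreement comparison (direct,
    complex resonance, disconnected-ligand resonance), oxidation-state
    and coordination-environment profiling, a deterministic toy-complex
    fixture generator, and batch drivers with structured logging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
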