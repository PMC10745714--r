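Package: glycotree
Title: Tree-Based Conformer Generation for Gas-Phase Oligosaccharides
Version: 0.1.0
Authors@R: person("Maintainer", "Glycotree", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs three-dimensional gas-phase conformers of
    oligosaccharides by a three-step tree-based sampling scheme: glycosidic
    linkage classes define the skeleton, inter-ring hydrogen-bond chain
    motifs select functional-group orientations, and cooperative chain
    directions (clockwise/counterclockwise) expand each motif group into
    its conformer variants.  Ships built-in motif catalogs for the
    N-glycan trisaccharides Man-beta(1,4)-GlcNAc-beta(1,4)-GlcNAc and
    trimannose, and block-combination strategies for the core
    pentasaccharide.  Includes a Cartesian/internal-coordinate geometry
    kernel, idealized pyranose residue templates, hydroxyl rotamer
    solving against a distance-based hydrogen-bond criterion, writers for
    XYZ/PDB coordinates and quantum-chemistry input decks, and
    post-processing of externally computed harmonic frequencies and
    energies (mode-type frequency scaling, Gaussian/Lorentzian band
    broadening, Boltzmann population weighting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
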