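Package: yrb
Title: Atom-Level Hydrophobicity and Charge Classification of Protein
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies every heavy atom of a protein structure into one of
    four chemical classes -- hydrophobic carbon (no bonded nitrogen or
    oxygen), negatively charged carboxylate oxygen (Asp/Glu side chains),
    positively charged amine/guanidinium nitrogen (Lys/Arg side chains),
    and neutral/polar everything else -- the "YRB" (yellow/red/blue)
    highlighting scheme used to visualize hydrophobicity and charge on
    protein surfaces at atomic resolution.  Reads PDB and mmCIF files,
    derives the classification from idealized residue topologies or by
    bond inference for non-standard residues, emits PyMOL and ChimeraX
    coloring scripts and class-encoded PDB files, computes Shrake-Rupley
    solvent-accessible surface areas per class, detects inter-chain salt
    bridges, and profiles protein-protein interfaces by buried area per
    class.  Includes a deterministic fixture generator (idealized residue
    templates, extended peptides, planted-contact dimers) so all analyses
    are testable without external structure files, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
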