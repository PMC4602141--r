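# yrb — atom-level hydrophobicity and charge classification of protein structures

Specificity in protein–protein interfaces comes from the matching of
hydrophobic patches and charged groups on the two sides of the contact.
Residue-level hydrophobicity scales blur this picture: the side chain of
arginine carries both an aliphatic stem that can pack hydrophobically and
a charged guanidinium head, and threonine's γ-methyl is hydrophobic while
its β-carbon, bound to a hydroxyl, is not.

The **YRB scheme** classifies every *heavy atom* of a protein into one of
four classes, using only the covalent structure of the residue:

| class | color | rule |
|---|---|---|
| hydrophobic | yellow | carbon atoms with **no** covalently bonded N or O |
| negative | red | side-chain carboxylate oxygens of Asp (OD1/OD2) and Glu (OE1/OE2) |
| positive | blue | side-chain nitrogens of Lys (NZ) and Arg (NE/NH1/NH2) |
| neutral | white | everything else, including the backbone N, CA, C, O |

Charges reflect typical protonation at physiological pH; histidine is
always treated as uncharged.  For the 20 standard amino acids the rule is
evaluated once over idealized residue topologies to produce a lookup
table; non-standard polymer residues (e.g. selenomethionine) fall back to
distance-based covalent-bond inference, which applies the carbon rule
only and never assigns a charge.

The package is aimed at structural biologists who want to assess or
visualize interface chemistry without a molecular-graphics session: it
reads PDB/mmCIF, writes PyMOL/ChimeraX coloring scripts and class-encoded
PDB files, and quantifies interfaces — Shrake–Rupley solvent-accessible
surface area (SASA) per class, inter-chain salt bridges (charged pairs),
and buried area per class on each side of a complex.

## Worked example

```r
library(yrb)

## a synthetic peptide containing each standard residue once
pep <- build_peptide("ACDEFGHIKLMNPQRSTVWY")
cl  <- classify_structure(pep)
cl
#> yrb_classified 'peptide': 168 atoms
#>  hydrophobic     negative     positive      neutral unclassified
#>           51            4            4          109            0
```

Of the 168 heavy atoms, 51 are hydrophobic carbons, the 4 negative atoms
are the Asp/Glu carboxylate oxygens, the 4 positive ones the Lys/Arg
side-chain nitrogens; the rest — polar side-chain groups and the entire
backbone — are neutral.  Atom-level resolution is visible within a single
arginine:

```r
subset(build_standard_table(), resname == "ARG")
#>    resname atom       class
#>        ARG   CB hydrophobic
#>        ARG   CG hydrophobic
#>        ARG   CD     neutral     # bound to NE
#>        ARG   NE    positive
#>        ARG   CZ     neutral     # bound to three nitrogens
#>        ARG  NH1    positive
#>        ARG  NH2    positive     # backbone/OXT rows omitted: neutral
```

Interface analysis on a two-chain fixture with a planted Lys–Asp contact:

```r
dimer <- build_planted_dimer("GKG", "GDG",
  contacts = list(list(res_a = 2, atom_a = "NZ",
                       res_b = 2, atom_b = "OD1", distance = 3.5)))

find_salt_bridges(dimer, "A", "B")          # default 4.0 Angstrom cutoff
#>   cat_chain cat_resid cat_resname cat_atom ani_chain ani_resid ani_resname ani_atom distance
#> 1         A         2         LYS       NZ         B         2         ASP      OD1      3.5

interface_atoms(dimer, "A", "B", n_points = 480)
#> yrb_interface A vs B (delta-sasa): 11/11 interface atoms,
#>   buried 99.6/87.6 A^2, 1 salt bridge(s)
```

The salt bridge is recovered at exactly its planted distance, and each
side buries ~90 Å² of accessible surface on complex formation.  A PyMOL
script reproducing the coloring:

```r
writeLines(head(write_pymol_script(cl, object_name = "all20"), 9))
#> ## yrb coloring scheme
#> set_color yrb_hydrophobic, [1.0000, 1.0000, 0.0000]
#> set_color yrb_negative, [1.0000, 0.0000, 0.0000]
#> set_color yrb_positive, [0.0000, 0.0000, 1.0000]
#> set_color yrb_neutral, [1.0000, 1.0000, 1.0000]
#> set_color yrb_unclassified, [0.7000, 0.7000, 0.7000]
#> set_color yrb_mask, [0.5000, 0.5000, 0.5000]
#> color yrb_hydrophobic, (all20 and chain A and resi 1 and name CB)
#> color yrb_neutral, (all20 and chain A and resi 1 and name N+CA+C+O)
```

## Command line

```sh
yrb classify structure.pdb --format tsv --out classes.tsv
yrb render structure.pdb --scheme yrb --mask 'chain A and 10-50' --out iface.pml
yrb interface complex.pdb --groups AB:C --out report.json --bridges-out bridges.tsv
yrb sasa structure.pdb --out sasa.tsv
yrb fixtures --dir fixtures
```

The `yrb` script is installed under the package's `exec/` directory
(`system.file("exec", "yrb", package = "yrb")`).  All subcommands are
deterministic: identical inputs give byte-identical outputs.

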