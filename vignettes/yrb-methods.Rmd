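---
title: "The YRB classification: model, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The YRB classification: model, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yrb)
```

## The classification model

YRB assigns each heavy atom of a protein one of four chemical classes.
The hydrophobicity half of the rule is purely topological: a carbon atom
is *hydrophobic* (yellow) if and only if none of its covalent bonding
partners is a nitrogen or an oxygen.  A CH~n~ group bound only to other
carbons (or to sulfur/selenium) can engage in hydrophobic packing; one
bound to an electronegative N or O is polarized and cannot.  The charge
half is a fixed physiological-pH convention: the side-chain carboxylate
oxygens of aspartate and glutamate are *negative* (red), the side-chain
amine/guanidinium nitrogens of lysine and arginine are *positive* (blue).
Histidine, whose pK~a~ sits near neutral pH, is always treated as
uncharged — the scheme does not attempt pK~a~ prediction or any
environment-dependent protonation.  Everything else, including the polar
backbone N, CA, C and O of every residue, is *neutral* (white).

For the 20 standard amino acids this rule is evaluated once over
idealized residue topologies (`residue_topology()`), giving a
187-entry lookup table (`build_standard_table()`) covering all heavy
atoms including the terminal OXT.  Classification of a structure
(`classify_structure()`) is then an exact table lookup per atom, which
makes it deterministic and total over heavy atoms.

```{r}
head(subset(build_standard_table(), resname == "THR"))
```

Threonine shows why atom-level resolution matters: CG2 is hydrophobic
while CB, bound to the hydroxyl oxygen, is not.

## Decisions where the rule is silent

Several cases are not fixed by the rule itself; the package resolves them
as follows, and exposes the choice where reasonable:

* **Terminal groups.**  The backbone convention covers N, CA, C, O; the
  termini are chemically charged at physiological pH but are not part of
  the side-chain charge rule.  By default OXT and the terminal oxygens
  are neutral like the rest of the backbone; `charged_termini = TRUE`
  marks the C-terminal carboxylate oxygens negative and the N-terminal
  nitrogen positive.
* **Sulfur and selenium.**  They are not carbon, so they are never
  yellow themselves (CYS SG, MET SD are neutral); carbons bonded only to
  them stay hydrophobic (CYS CB, MET CG/CE), because the rule excludes
  only nitrogen and oxygen partners.
* **Non-standard polymer residues** (selenomethionine and other
  modified amino acids, recognized by their N/CA/C backbone) fall back to
  distance-based bond inference: two atoms are bonded iff their distance
  is at most the sum of their covalent radii plus a 0.45 Å tolerance (a
  common heuristic; configurable via `bond_tol`).  The fallback applies
  the carbon rule only — it never assigns a charge, since charge
  assignment requires knowing the group's protonation, which topology
  alone does not give.
* **Hetero compounds, waters and ions** are outside the scheme and are
  neutral under the default policy; an element-based CPK comparison
  scheme is available for ligands.
* **Alternate locations** are resolved at read time to the
  highest-occupancy variant (ties broken by file order), and only the
  first coordinate model of an ensemble is kept.

## Rendering

The published palette is defined with RGB values that are not printed
anywhere, so the defaults here are openly declared pure primaries —
yellow (1,1,0), red (1,0,0), blue (0,0,1), white (1,1,1) — overridable
through a key=value config file.  Byte-identical colors with the original
script are explicitly not a goal.  Scripts group atoms per residue and
class in a fixed (chain, residue, class) order so output is byte-stable,
and every heavy atom is covered by exactly one color command; parsing an
emitted script back (`parse_pymol_script()`, `parse_chimerax_script()`)
recovers the exact atom→class map, which the test suite uses as a
round-trip invariant.  Masking recolors whole excluded residues with
gray50, reproducing the interface-only display workflow.  For exchange
with other tools, classes can be written into the PDB B-factor column as
integer codes (neutral 0, hydrophobic 1, negative 2, positive 3,
unclassified 9).

## Surface areas and interfaces

SASA uses the Shrake–Rupley construction: each atom's van der Waals
sphere (Bondi radii: C 1.70, N 1.55, O 1.52, S 1.80 Å) is expanded by
the probe radius (1.4 Å, water) and sampled with a deterministic
golden-spiral point set — no RNG, so areas are bit-stable.  The default
960 points give an isolated-sphere error well below 1% and a change of
under 0.5% on doubling; per-class areas are exact partitions of the
total by construction.

Interfaces are quantified by delta-SASA: an atom's buried area is its
accessible area in its own chain group alone minus its area in the
complex; a side's buried area is the sum of positive per-atom burials.
A distance criterion (any opposite-group heavy atom within 5 Å) is
available as a cheaper alternative for selecting interface atoms.

Salt bridges (charged pairs) are contacts between a Lys/Arg side-chain
nitrogen and an Asp/Glu side-chain oxygen across the two chain groups.
The geometric criterion is a minimal N–O distance of 4.0 Å — the common
literature convention, configurable.  Pairs are counted at residue
level: the chemically equivalent NH1/NH2 and OD1/OD2 (or OE1/OE2) atoms
are deduplicated and the minimal-distance atom pair is reported, so one
guanidinium–carboxylate contact is one pair.  Histidine is excluded as a
donor, consistent with its uncharged treatment.  The implementation uses
a grid-based neighbor search; the tests hold it equal to an exhaustive
all-pairs scan and verify monotonicity in the cutoff.

## The fixture generator

All tests run offline on synthetic structures with known ground truth:

* **Residue templates** store heavy-atom internal coordinates (standard
  bond lengths and angles) and a reference bond list; realizing a
  template and re-inferring bonds from distances must reproduce that
  list exactly, which ties the geometric and topological views of each
  residue together.
* **Peptides** are built in an extended conformation (φ = ψ = ω = 180°),
  chosen so that sequences are clash-free without any conformational
  search; proline is the exception — its pyrrolidine ring closes through
  the backbone nitrogen and cannot adopt φ = 180°, so proline residues
  use φ = −70°, within its sterically allowed range.  Acyclic side-chain
  torsions are all-trans, with terminal carboxamide/carboxylate and
  aromatic-ring torsions rotated out of the backbone plane for the same
  clash-freedom.
* **Planted dimers** place a second chain as a rigid body so that
  requested inter-chain atom pairs sit at prescribed distances (within
  0.05 Å) with no inter-chain contact below 2 Å.  Placement is a
  rigid-body least-squares fit from seeded random restarts, so it is
  deterministic per seed.  Note that planting, say, Lys NZ at 3.5 Å from
  Asp OD1 leaves OD2 free; the reported bridge is the minimal-distance
  atom pair and can be shorter than the planted distance.

These fixtures emulate connectivity and controlled geometry, not
conformational realism: there is no rotamer sampling, no energy
minimization, and no crystallographic disorder, B-factor structure,
missing atoms or solvent.  Tests passing on them demonstrate the
correctness of classification, geometry and bookkeeping — not robustness
to every pathology of experimental coordinate files, although altloc
resolution, element inference from atom names and hydrogen stripping are
exercised on hand-crafted PDB records.

## Problem sizes and tolerances

The test and acceptance runs use the all-residue 20-mer (168 heavy
atoms), planted dimers of 3–5 residues per chain, and SASA point counts
of 120–960, which keep the full suite in the tens of seconds on one
core while leaving the numerical checks meaningful: isolated-sphere SASA
within 1% of the closed form, point-doubling drift under 0.5%, exact
per-class partition, planted distances within 0.05 Å, and exact
(byte-level) reproducibility of all command-line outputs.

## Known limitations

* The classification is static: conformational dynamics, burial-dependent
  effective pK~a~s and ligand-induced changes are out of scope, as are
  electrostatic-potential maps and hydrogen-bond networks.
* The charged-pair criterion is geometric only; it does not distinguish
  solvent-exposed from buried bridges and uses a single distance cutoff.
* Bond inference is distance-based and can be fooled by severely
  distorted coordinates; for standard residues the table path is
  authoritative and inference is only a fallback.
* Analyses of published complexes require the corresponding PDB entries;
  the package does not redistribute them and only fetches on explicit
  request.
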