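## Idealized heavy-atom residue templates.
##
## Each template lists the side-chain atoms of one residue as internal
## coordinates (parent / angle-reference / torsion-reference atoms, bond
## length in Angstrom, bond angle and torsion in degrees) plus the
## reference covalent bond list among heavy atoms.  Backbone atoms
## (N, CA, C, O, OXT) are placed by the peptide builder.  Geometry uses
## standard bond lengths/angles (Engh-Huber-like values); acyclic torsions
## are all-trans so realized templates are extended and clash-free.
##
## The bond list is the ground truth against which distance-based bond
## inference is validated, and the substrate from which the standard YRB
## classification table is derived.

## helper: one side-chain atom row
.sc <- function(name, elem, p, q, r, b, ang, dih) {
  data.frame(name = name, elem = elem, p = p, q = q, r = r,
             b = b, ang = ang, dih = dih, stringsAsFactors = FALSE)
}

.CB <- function(b = 1.53, ang = 110.5) .sc("CB", "C", "CA", "N", "C", b, ang, -122.5)

RESIDUE_TEMPLATES <- local({
  t <- list()

  t$ALA <- list(
    sc = .CB(1.52),
    sc_bonds = list(c("CA", "CB"))
  )
  t$ARG <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("CD",  "C", "CG", "CB", "CA", 1.52, 111.0, 180),
      .sc("NE",  "N", "CD", "CG", "CB", 1.46, 112.0, 180),
      .sc("CZ",  "C", "NE", "CD", "CG", 1.33, 124.0, 180),
      .sc("NH1", "N", "CZ", "NE", "CD", 1.33, 120.0, 0),
      .sc("NH2", "N", "CZ", "NE", "CD", 1.33, 120.0, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "NE"), c("NE", "CZ"), c("CZ", "NH1"),
                    c("CZ", "NH2"))
  )
  t$ASN <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.52, 112.6, 180),
      .sc("OD1", "O", "CG", "CB", "CA", 1.23, 120.8, 90),
      .sc("ND2", "N", "CG", "CB", "CA", 1.33, 116.4, -90)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"),
                    c("CG", "ND2"))
  )
  t$ASP <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.52, 112.6, 180),
      .sc("OD1", "O", "CG", "CB", "CA", 1.25, 118.4, 90),
      .sc("OD2", "O", "CG", "CB", "CA", 1.25, 118.4, -90)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"),
                    c("CG", "OD2"))
  )
  t$CYS <- list(
    sc = rbind(
      .CB(),
      .sc("SG", "S", "CB", "CA", "N", 1.81, 114.4, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "SG"))
  )
  t$GLN <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("CD",  "C", "CG", "CB", "CA", 1.52, 112.6, 180),
      .sc("OE1", "O", "CD", "CG", "CB", 1.23, 120.8, 90),
      .sc("NE2", "N", "CD", "CG", "CB", 1.33, 116.4, -90)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "OE1"), c("CD", "NE2"))
  )
  t$GLU <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("CD",  "C", "CG", "CB", "CA", 1.52, 112.6, 180),
      .sc("OE1", "O", "CD", "CG", "CB", 1.25, 118.4, 90),
      .sc("OE2", "O", "CD", "CG", "CB", 1.25, 118.4, -90)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "OE1"), c("CD", "OE2"))
  )
  t$GLY <- list(sc = NULL, sc_bonds = list())
  t$HIS <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.50, 113.8, 180),
      .sc("ND1", "N", "CG", "CB", "CA", 1.38, 122.7, 90),
      .sc("CD2", "C", "CG", "CB", "CA", 1.36, 131.1, -90),
      .sc("CE1", "C", "ND1", "CG", "CB", 1.32, 109.3, 180),
      .sc("NE2", "N", "CD2", "CG", "CB", 1.37, 107.1, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"),
                    c("CG", "CD2"), c("ND1", "CE1"), c("CD2", "NE2"),
                    c("CE1", "NE2"))
  )
  t$ILE <- list(
    sc = rbind(
      .CB(1.54, 111.5),
      .sc("CG1", "C", "CB", "CA", "N",  1.53, 110.4, 180),
      .sc("CG2", "C", "CB", "CA", "N",  1.53, 110.5, -60),
      .sc("CD1", "C", "CG1", "CB", "CA", 1.51, 113.8, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"),
                    c("CG1", "CD1"))
  )
  t$LEU <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.53, 116.3, 180),
      .sc("CD1", "C", "CG", "CB", "CA", 1.52, 110.5, 180),
      .sc("CD2", "C", "CG", "CB", "CA", 1.52, 110.5, 60)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                    c("CG", "CD2"))
  )
  t$LYS <- list(
    sc = rbind(
      .CB(),
      .sc("CG", "C", "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("CD", "C", "CG", "CB", "CA", 1.52, 111.0, 180),
      .sc("CE", "C", "CD", "CG", "CB", 1.52, 111.0, 180),
      .sc("NZ", "N", "CE", "CD", "CG", 1.49, 112.0, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "CE"), c("CE", "NZ"))
  )
  t$MET <- list(
    sc = rbind(
      .CB(),
      .sc("CG", "C", "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("SD", "S", "CG", "CB", "CA", 1.80, 112.7, 180),
      .sc("CE", "C", "SD", "CG", "CB", 1.79, 100.9, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"),
                    c("SD", "CE"))
  )
  t$PHE <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.50, 113.8, 180),
      .sc("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, 90),
      .sc("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, -90),
      .sc("CE1", "C", "CD1", "CG", "CB", 1.39, 120.0, 180),
      .sc("CE2", "C", "CD2", "CG", "CB", 1.39, 120.0, 180),
      .sc("CZ",  "C", "CE1", "CD1", "CG", 1.39, 120.0, 0)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                    c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
                    c("CE1", "CZ"), c("CE2", "CZ"))
  )
  t$PRO <- list(
    ## planar five-membered ring closed through the backbone nitrogen
    sc = rbind(
      .sc("CB", "C", "CA", "N", "C", 1.53, 107.3, -120),
      .sc("CG", "C", "CB", "CA", "N", 1.50, 107.3, 0),
      .sc("CD", "C", "CG", "CB", "CA", 1.51, 107.3, 0)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "N"))
  )
  t$SER <- list(
    sc = rbind(
      .CB(),
      .sc("OG", "O", "CB", "CA", "N", 1.42, 110.8, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "OG"))
  )
  t$THR <- list(
    sc = rbind(
      .CB(1.54, 111.5),
      .sc("OG1", "O", "CB", "CA", "N", 1.43, 109.6, 180),
      .sc("CG2", "C", "CB", "CA", "N", 1.52, 110.5, -60)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2"))
  )
  t$TRP <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",   1.50, 113.6, 180),
      .sc("CD1", "C", "CG", "CB", "CA",  1.37, 126.9, 75),
      .sc("CD2", "C", "CG", "CB", "CA",  1.43, 126.8, -105),
      .sc("NE1", "N", "CD1", "CG", "CB", 1.38, 110.2, 180),
      .sc("CE2", "C", "CD2", "CG", "CB", 1.41, 107.2, 180),
      .sc("CE3", "C", "CD2", "CG", "CB", 1.40, 133.9, 0),
      .sc("CZ2", "C", "CE2", "CD2", "CG", 1.40, 122.4, 180),
      .sc("CZ3", "C", "CE3", "CD2", "CG", 1.39, 118.6, 180),
      .sc("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117.5, 0)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                    c("CG", "CD2"), c("CD1", "NE1"), c("NE1", "CE2"),
                    c("CD2", "CE2"), c("CD2", "CE3"), c("CE2", "CZ2"),
                    c("CE3", "CZ3"), c("CZ2", "CH2"), c("CZ3", "CH2"))
  )
  t$TYR <- list(
    sc = rbind(
      .CB(),
      .sc("CG",  "C", "CB", "CA", "N",  1.51, 113.9, 180),
      .sc("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, 90),
      .sc("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, -90),
      .sc("CE1", "C", "CD1", "CG", "CB", 1.39, 121.1, 180),
      .sc("CE2", "C", "CD2", "CG", "CB", 1.39, 121.1, 180),
      .sc("CZ",  "C", "CE1", "CD1", "CG", 1.38, 119.6, 0),
      .sc("OH",  "O", "CZ", "CE1", "CD1", 1.38, 119.9, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                    c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
                    c("CE1", "CZ"), c("CE2", "CZ"), c("CZ", "OH"))
  )
  t$VAL <- list(
    sc = rbind(
      .CB(1.54, 111.5),
      .sc("CG1", "C", "CB", "CA", "N", 1.52, 110.5, 180),
      .sc("CG2", "C", "CB", "CA", "N", 1.52, 110.5, -60)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
  )

  ## Selenomethionine: non-standard polymer residue used to exercise the
  ## bond-inference fallback (Se is neither N nor O, so CG/CE stay
  ## hydrophobic under the carbon rule).
  t$MSE <- list(
    sc = rbind(
      .CB(),
      .sc("CG", "C",  "CB", "CA", "N",  1.52, 114.0, 180),
      .sc("SE", "SE", "CG", "CB", "CA", 1.95, 112.7, 180),
      .sc("CE", "C",  "SE", "CG", "CB", 1.94, 100.9, 180)
    ),
    sc_bonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SE"),
                    c("SE", "CE"))
  )

  t
})

## Three-letter codes of the 20 standard amino acids, alphabetical.
STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Residue codes with an idealized template
#'
#' @param standard_only logical; restrict to the 20 standard amino acids.
#' @return character vector of three-letter residue codes.
#' @export
#' @examples
#' list_residue_templates()
list_residue_templates <- function(standard_only = FALSE) {
  if (standard_only) STANDARD_RESIDUES else names(RESIDUE_TEMPLATES)
}

#' Idealized topology of a templated residue
#'
#' Returns the residue's heavy atoms (with elements) and its reference
#' covalent bond list, including the backbone bonds and, when
#' `terminal = TRUE`, the C-OXT bond.  This is the topology the standard
#' classification table is derived from.
#'
#' @param code three-letter residue code (e.g. `"ARG"`).
#' @param terminal logical; include the terminal carboxylate oxygen OXT.
#' @return a list with class `"yrb_topology"`: `code`, `atoms`
#'   (data.frame with `name`, `elem`) and `bonds` (two-column character
#'   matrix, symmetric closure not materialized).
#' @export
#' @examples
#' residue_topology("ALA")$bonds
residue_topology <- function(code, terminal = FALSE) {
  code <- toupper(code)
  tpl <- RESIDUE_TEMPLATES[[code]]
  if (is.null(tpl)) stop("no residue template for code '", code, "'")
  atoms <- data.frame(
    name = c("N", "CA", "C", "O"),
    elem = c("N", "C", "C", "O"),
    stringsAsFactors = FALSE
  )
  if (!is.null(tpl$sc)) {
    atoms <- rbind(atoms, tpl$sc[, c("name", "elem")])
  }
  bonds <- rbind(
    c("N", "CA"), c("CA", "C"), c("C", "O"),
    do.call(rbind, tpl$sc_bonds)
  )
  if (terminal) {
    atoms <- rbind(atoms, data.frame(name = "OXT", elem = "O"))
    bonds <- rbind(bonds, c("C", "OXT"))
  }
  structure(list(code = code, atoms = atoms, bonds = bonds),
            class = "yrb_topology")
}
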