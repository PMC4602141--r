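## YRB atom classification.
##
## The rule, applied at physiological-pH protonation (histidine always
## uncharged):
##   * a carbon with no covalently bonded nitrogen or oxygen -> hydrophobic
##   * side-chain oxygens of ASP (OD1/OD2) and GLU (OE1/OE2)  -> negative
##   * side-chain nitrogens of LYS (NZ) and ARG (NE/NH1/NH2)  -> positive
##   * every other heavy atom, including backbone N/CA/C/O    -> neutral
##
## For the 20 standard residues the rule is evaluated once over idealized
## residue topologies to produce a lookup table; non-standard polymer
## residues fall back to distance-based bond inference, which applies the
## carbon rule only (never assigns a charge).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## Apply the YRB rule to one residue topology: named character vector of
## classes over the topology's atoms.
apply_yrb_rule <- function(topology) {
  atoms <- topology$atoms
  bonds <- topology$bonds
  elem <- setNames(atoms$elem, atoms$name)
  cls <- setNames(rep("neutral", nrow(atoms)), atoms$name)
  side <- setdiff(atoms$name, BACKBONE_ATOMS)
  if (topology$code %in% c("ASP", "GLU")) {
    cls[side[elem[side] == "O"]] <- "negative"
  }
  if (topology$code %in% c("LYS", "ARG")) {
    cls[side[elem[side] == "N"]] <- "positive"
  }
  for (nm in atoms$name[atoms$elem == "C"]) {
    partners <- c(bonds[bonds[, 1] == nm, 2], bonds[bonds[, 2] == nm, 1])
    if (!any(elem[partners] %in% c("N", "O"))) cls[nm] <- "hydrophobic"
  }
  cls
}

#' Build the standard YRB classification table
#'
#' Applies the classification rule to the idealized topologies of the 20
#' standard amino acids, covering all heavy atoms including backbone and
#' the terminal OXT (neutral by default; see `charged_termini` in
#' [classify_structure()] for the alternative convention).
#'
#' @return a data.frame of class `"yrb_table"` with columns `resname`,
#'   `atom`, `class`.
#' @export
#' @examples
#' tab <- build_standard_table()
#' subset(tab, resname == "ARG")
build_standard_table <- function() {
  rows <- lapply(STANDARD_RESIDUES, function(code) {
    cls <- apply_yrb_rule(residue_topology(code, terminal = TRUE))
    data.frame(resname = code, atom = names(cls), class = unname(cls),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("yrb_table", "data.frame")
  tab
}

## fast lookup vector "RES|ATOM" -> class
.table_lookup <- function(table) {
  setNames(table$class, paste(table$resname, table$atom, sep = "|"))
}

#' Look up the YRB class of (residue, atom name) pairs
#'
#' Exact table lookup; pairs absent from the table return
#' `"unclassified"` (the caller decides any fallback).
#'
#' @param resname character vector of three-letter residue codes.
#' @param atom character vector of PDB atom names (recycled pairwise with
#'   `resname`).
#' @param table a classification table from [build_standard_table()].
#' @return character vector of class labels.
#' @export
#' @examples
#' classify_atom("GLU", "OE1")
#' classify_atom("XYZ", "C1")
classify_atom <- function(resname, atom, table = build_standard_table()) {
  lk <- .table_lookup(table)
  out <- unname(lk[paste(toupper(resname), toupper(atom), sep = "|")])
  out[is.na(out)] <- "unclassified"
  out
}

#' Infer covalent bonds within a residue from interatomic distances
#'
#' Two atoms are bonded iff their distance does not exceed the sum of
#' their covalent radii plus `tol`.  Symmetric, no self bonds.
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`
#'   (one residue's heavy atoms).
#' @param tol distance tolerance added to the summed covalent radii
#'   (Angstrom); 0.45 is a common heuristic.
#' @return two-column character matrix of bonded atom-name pairs
#'   (each undirected bond listed once).
#' @export
#' @examples
#' res <- build_residue("ALA")
#' infer_bonds(res$atoms)
infer_bonds <- function(atoms, tol = 0.45) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  radii <- covalent_radius(atoms$element)
  if (anyNA(radii))
    stop("no covalent radius for atom(s): ",
         paste(atoms$name[is.na(radii)], " (element '",
               atoms$element[is.na(radii)], "')", sep = "", collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 1) return(matrix(character(0), ncol = 2))
  d <- cross_distances(xyz, xyz)
  cut <- outer(radii, radii, "+") + tol
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  cbind(atoms$name[hit[, 1]], atoms$name[hit[, 2]])
}

## Is a residue polymer-like (has the protein backbone triad)?
.is_polymer_residue <- function(atom_names) {
  all(c("N", "CA", "C") %in% atom_names)
}

#' Classify every heavy atom of a structure
#'
#' Standard residues are classified by table lookup.  Non-standard polymer
#' residues (those with an N/CA/C backbone, e.g. selenomethionine) are
#' handled per `fallback`: `"bond-inference"` infers covalent bonds from
#' distances and applies the carbon rule only (a carbon is hydrophobic iff
#' it has no bonded N or O; nothing is ever charged by inference),
#' `"neutral"` marks all their atoms neutral, `"skip"` leaves them
#' unclassified.  Hetero compounds and waters are neutral under the
#' default policy (ligands are outside the YRB scheme).
#'
#' @param model a hydrogen-free [yrb_structure()].
#' @param table classification table (default [build_standard_table()]).
#' @param fallback policy for non-standard polymer residues.
#' @param charged_termini logical; if `TRUE`, chain-terminal carboxylate
#'   oxygens (OXT and the O of the last residue) are marked negative and
#'   the N-terminal backbone nitrogen positive.  Default `FALSE`: termini
#'   are neutral like the rest of the backbone.
#' @param bond_tol tolerance for bond inference, Angstrom.
#' @return an object of class `"yrb_classified"`: list with `model`,
#'   `classes` (character, one per atom) and `provenance` (one of
#'   `"table"`, `"bond-inference"`, `"policy-default"`).
#' @export
#' @examples
#' cl <- classify_structure(build_peptide("ADE"))
#' class_composition(cl)
classify_structure <- function(model,
                               table = build_standard_table(),
                               fallback = c("bond-inference", "neutral", "skip"),
                               charged_termini = FALSE,
                               bond_tol = 0.45) {
  stopifnot(inherits(model, "yrb_structure"))
  fallback <- match.arg(fallback)
  a <- model$atoms
  if (any(a$element %in% c("H", "D")))
    stop("model contains hydrogens; run strip_hydrogens() first")
  n <- nrow(a)
  classes <- rep("unclassified", n)
  prov <- rep("policy-default", n)
  if (n > 0) {
    lk <- .table_lookup(table)
    tabled <- unique(table$resname)
    rkey <- residue_key(a)
    for (key in unique(rkey)) {
      idx <- which(rkey == key)
      resname <- a$resname[idx[1]]
      standard <- resname %in% tabled
      polymer <- .is_polymer_residue(a$name[idx])
      if (!standard && !polymer) {
        ## hetero compounds, waters, ions: outside the scheme
        classes[idx] <- "neutral"
        prov[idx] <- "policy-default"
        next
      }
      hit <- if (standard) unname(lk[paste(resname, a$name[idx], sep = "|")])
             else rep(NA_character_, length(idx))
      classes[idx] <- ifelse(is.na(hit), "unclassified", hit)
      prov[idx] <- ifelse(is.na(hit), "policy-default", "table")
      miss <- idx[is.na(hit)]
      if (length(miss) == 0) next
      if (fallback == "neutral") {
        classes[miss] <- "neutral"
      } else if (fallback == "bond-inference") {
        res_atoms <- a[idx, c("name", "element", "x", "y", "z")]
        bonds <- infer_bonds(res_atoms, tol = bond_tol)
        elem <- setNames(res_atoms$element, res_atoms$name)
        for (j in miss) {
          nm <- a$name[j]
          if (a$element[j] == "C") {
            partners <- c(bonds[bonds[, 1] == nm, 2],
                          bonds[bonds[, 2] == nm, 1])
            classes[j] <- if (any(elem[partners] %in% c("N", "O")))
              "neutral" else "hydrophobic"
          } else {
            classes[j] <- "neutral"
          }
          prov[j] <- "bond-inference"
        }
      } ## "skip": leave unclassified
    }
    if (charged_termini) {
      res <- residue_table(model)
      polymer_key <- paste(a$chain, a$resid, a$icode, sep = "|")
      for (ch in unique(res$chain)) {
        rc <- res[res$chain == ch, , drop = FALSE]
        poly <- vapply(seq_len(nrow(rc)), function(i) {
          idx <- which(polymer_key == paste(ch, rc$resid[i], rc$icode[i], sep = "|"))
          .is_polymer_residue(a$name[idx])
        }, logical(1))
        rc <- rc[poly, , drop = FALSE]
        if (nrow(rc) == 0) next
        first_key <- paste(ch, rc$resid[1], rc$icode[1], sep = "|")
        last_key <- paste(ch, rc$resid[nrow(rc)], rc$icode[nrow(rc)], sep = "|")
        nterm <- which(polymer_key == first_key & a$name == "N")
        cterm <- which(polymer_key == last_key & a$name %in% c("O", "OXT"))
        classes[nterm] <- "positive"
        classes[cterm] <- "negative"
        prov[c(nterm, cterm)] <- "policy-default"
      }
    }
  }
  structure(list(model = model, classes = classes, provenance = prov),
            class = "yrb_classified")
}

#' @export
print.yrb_classified <- function(x, ...) {
  cat(sprintf("yrb_classified '%s': %d atoms\n", x$model$id, natoms(x$model)))
  print(class_composition(x))
  invisible(x)
}

#' Count atoms per YRB class
#'
#' @param classified a [classify_structure()] result.
#' @return named integer vector over all five class labels; counts sum to
#'   the number of atoms.
#' @export
class_composition <- function(classified) {
  stopifnot(inherits(classified, "yrb_classified"))
  counts <- table(factor(classified$classes, levels = YRB_CLASSES_ALL))
  out <- as.integer(counts)
  names(out) <- YRB_CLASSES_ALL
  out
}

#' Export a per-atom classification as JSON or TSV
#'
#' One record per atom with residue identity (chain, resid, insertion
#' code, residue name), atom name, class and provenance.
#'
#' @param classified a [classify_structure()] result.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_classification <- function(classified, path,
                                  format = c("json", "tsv")) {
  format <- match.arg(format)
  a <- classified$model$atoms
  df <- data.frame(
    chain = a$chain, resid = a$resid, icode = a$icode,
    resname = a$resname, atom = a$name,
    class = classified$classes, provenance = classified$provenance,
    stringsAsFactors = FALSE
  )
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
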