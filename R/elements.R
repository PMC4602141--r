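## Element handling: symbol normalization, inference from PDB atom names,
## covalent radii (bond inference) and van der Waals radii (SASA).

## Covalent radii in Angstrom (Cordero et al. 2008 single-bond values,
## rounded), for the elements that occur in protein structures and common
## ligands.
COVALENT_RADII <- c(
  H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, SE = 1.20,
  P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, B = 0.84,
  FE = 1.32, ZN = 1.22, MG = 1.41, MN = 1.39, CU = 1.32, NI = 1.24,
  CO = 1.26, CA = 1.76, "NA" = 1.66, K = 2.03
)

## Bondi (1964) van der Waals radii; the protein-atom subset C/N/O/S is the
## package default radii set for Shrake-Rupley SASA.
BONDI_VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
  P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

#' Normalize an element symbol
#'
#' Upper-cases and trims an element symbol string (`"Se"`, `" c"` ->
#' `"SE"`, `"C"`).
#'
#' @param element character vector of element symbols.
#' @return normalized character vector.
#' @keywords internal
normalize_element <- function(element) {
  toupper(trimws(element))
}

#' Infer element symbols from PDB atom names
#'
#' Used when the element column of a coordinate file is blank.  Follows the
#' PDB v3 atom-name convention: hydrogen names may carry a leading digit
#' (`"1HG1"`, `"2HB"`) or start with `H` followed by more characters
#' (`"HB2"`); otherwise the element is the leading alphabetic part of the
#' name, checked against the known two-letter symbols (`"SE"`, `"FE"`, ...)
#' before falling back to the first letter.
#'
#' @param name character vector of PDB atom names.
#' @param resname optional residue names (three-letter codes), used to
#'   disambiguate e.g. the `SE` atom of selenomethionine.
#' @return character vector of element symbols.
#' @export
#' @examples
#' infer_element(c("CA", "NH1", "1HG1", "HB2", "OXT"))
infer_element <- function(name, resname = NULL) {
  name <- toupper(trimws(name))
  out <- character(length(name))
  two_letter <- c("SE", "FE", "ZN", "MG", "MN", "CU", "NI", "CO", "CL",
                  "BR", "NA")
  for (i in seq_along(name)) {
    nm <- name[i]
    if (grepl("^[0-9]*[HD]", nm) && nzchar(sub("^[0-9]*", "", nm))) {
      ## digit-prefixed or plain hydrogen/deuterium names ("1HG1", "HB2",
      ## "HA") -- but bare metal names like "HG" (mercury) never occur in
      ## ATOM records of amino acids, so H wins for polymer atoms.
      out[i] <- substr(sub("^[0-9]*", "", nm), 1, 1)
      next
    }
    alpha <- sub("^[0-9]*", "", nm)
    head2 <- substr(alpha, 1, 2)
    if (head2 %in% two_letter &&
        (nchar(alpha) == 2 ||
         (!is.null(resname) && head2 == "SE" && resname[i] == "MSE"))) {
      out[i] <- head2
    } else {
      out[i] <- substr(alpha, 1, 1)
    }
  }
  out
}

#' Covalent radius of an element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom); `NA` for unknown elements.
#' @export
covalent_radius <- function(element) {
  unname(COVALENT_RADII[normalize_element(element)])
}

#' Van der Waals radius of an element (Bondi set)
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom); `NA` for unknown elements.
#' @export
vdw_radius <- function(element) {
  unname(BONDI_VDW_RADII[normalize_element(element)])
}
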