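## Selection-expression mini-grammar for masks.
##
## Grammar (case-insensitive keywords):
##   selection := clause (" or " clause)*
##   clause    := term (" and " term)*
##   term      := "chain" <id> | ["resi"] <ranges>
##   ranges    := range ("," range)* ;  range := <n> | <n>-<m>
## Examples: "chain A", "chain A and 10-50", "chain A and resi 1-5,9 or chain B"

#' Parse a residue selection expression against a model
#'
#' @param expr selection string (see grammar above).
#' @param model a [yrb_structure()] the selection applies to.
#' @return data.frame of selected residues (`chain`, `resid`, `icode`),
#'   suitable as the `mask` of [write_pymol_script()].
#' @export
#' @examples
#' parse_selection("chain A and 2-3", build_peptide("ACDE"))
parse_selection <- function(expr, model) {
  stopifnot(is.character(expr), length(expr) == 1)
  res <- residue_table(model)
  if (!nzchar(trimws(expr))) stop("empty selection expression")
  selected <- rep(FALSE, nrow(res))
  for (clause in strsplit(expr, "\\s+or\\s+|;", perl = TRUE)[[1]]) {
    keep <- rep(TRUE, nrow(res))
    terms <- strsplit(trimws(clause), "\\s+and\\s+", perl = TRUE)[[1]]
    if (length(terms) == 0 || !nzchar(terms[1]))
      stop("cannot parse selection clause: '", clause, "'")
    for (term in trimws(terms)) {
      if (grepl("^chain\\s+\\S+$", term, ignore.case = TRUE)) {
        id <- sub("^chain\\s+", "", term, ignore.case = TRUE)
        keep <- keep & res$chain == id
      } else {
        ranges <- sub("^resi\\s+", "", term, ignore.case = TRUE)
        if (!grepl("^[0-9]+(-[0-9]+)?(,[0-9]+(-[0-9]+)?)*$", ranges))
          stop("cannot parse selection term: '", term, "'")
        in_ranges <- rep(FALSE, nrow(res))
        for (rg in strsplit(ranges, ",")[[1]]) {
          lim <- as.integer(strsplit(rg, "-")[[1]])
          if (length(lim) == 1) lim <- c(lim, lim)
          in_ranges <- in_ranges | (res$resid >= lim[1] & res$resid <= lim[2])
        }
        keep <- keep & in_ranges
      }
    }
    selected <- selected | keep
  }
  out <- res[selected, c("chain", "resid", "icode")]
  rownames(out) <- NULL
  out
}
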