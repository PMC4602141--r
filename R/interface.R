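## Interface analyses: inter-group salt bridges (charged pairs), interface
## atom detection, and per-class buried surface area.

## side-chain charged atoms at physiological pH; histidine is uncharged
## throughout and never contributes
CATION_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.charged_atom_rows <- function(atoms, which = c("cation", "anion")) {
  which <- match.arg(which)
  spec <- if (which == "cation") CATION_ATOMS else ANION_ATOMS
  sel <- rep(FALSE, nrow(atoms))
  for (res in names(spec)) {
    sel <- sel | (atoms$resname == res & atoms$name %in% spec[[res]])
  }
  which(sel)
}

.check_groups <- function(model, group_a, group_b) {
  chains <- unique(model$atoms$chain)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("chain groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  unknown <- setdiff(c(group_a, group_b), chains)
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
}

## grid-based neighbor pairs: indices (i into xa rows, j into xb rows)
## with distance <= cutoff
.grid_neighbor_pairs <- function(xa, xb, cutoff) {
  if (nrow(xa) == 0 || nrow(xb) == 0)
    return(matrix(integer(0), ncol = 2))
  cell <- function(x) floor(x / cutoff)
  ka <- cell(xa); kb <- cell(xb)
  keyb <- paste(kb[, 1], kb[, 2], kb[, 3])
  index <- split(seq_len(nrow(xb)), keyb)
  out <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(xa))) {
    cand <- integer(0)
    for (k in seq_len(nrow(offs))) {
      key <- paste(ka[i, 1] + offs[k, 1], ka[i, 2] + offs[k, 2],
                   ka[i, 3] + offs[k, 3])
      cand <- c(cand, index[[key]])
    }
    if (length(cand) == 0) next
    d <- sqrt(colSums((t(xb[cand, , drop = FALSE]) - xa[i, ])^2))
    hit <- cand[d <= cutoff]
    if (length(hit))
      out[[length(out) + 1]] <- cbind(i, hit)
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' Find inter-group salt bridges (charged pairs)
#'
#' A salt bridge is a contact between a positively charged side-chain
#' nitrogen (Lys NZ; Arg NE/NH1/NH2) in one chain group and a negatively
#' charged side-chain oxygen (Asp OD1/OD2; Glu OE1/OE2) in the other,
#' with minimal N-O distance at most `cutoff`.  Pairs are counted at
#' residue level: the equivalent carboxylate/guanidinium atoms are
#' deduplicated and the minimal-distance atom pair is reported.
#' Histidine never contributes.  Symmetric in the two groups.
#'
#' @param model a [yrb_structure()].
#' @param group_a,group_b disjoint, non-empty character vectors of chain
#'   ids.
#' @param cutoff distance criterion, Angstrom; 4.0 is the common
#'   literature convention for side-chain charged-group contacts.
#' @return data.frame of class `"yrb_salt_bridges"`, one row per residue
#'   pair, sorted by (cation chain, residue, anion chain, residue):
#'   columns `cat_chain`, `cat_resid`, `cat_icode`, `cat_resname`,
#'   `cat_atom`, `ani_chain`, `ani_resid`, `ani_icode`, `ani_resname`,
#'   `ani_atom`, `distance`.
#' @export
#' @examples
#' dim <- build_planted_dimer("GKG", "GDG",
#'   contacts = list(list(res_a = 2, atom_a = "NZ",
#'                        res_b = 2, atom_b = "OD1", distance = 3.5)))
#' find_salt_bridges(dim, "A", "B")
find_salt_bridges <- function(model, group_a, group_b, cutoff = 4.0) {
  stopifnot(inherits(model, "yrb_structure"), cutoff > 0)
  .check_groups(model, group_a, group_b)
  a <- model$atoms
  empty <- data.frame(
    cat_chain = character(0), cat_resid = integer(0),
    cat_icode = character(0), cat_resname = character(0),
    cat_atom = character(0),
    ani_chain = character(0), ani_resid = integer(0),
    ani_icode = character(0), ani_resname = character(0),
    ani_atom = character(0), distance = numeric(0),
    stringsAsFactors = FALSE
  )
  rows <- list()
  ## cations can sit in either group; scan both directions
  for (dir in 1:2) {
    gc <- if (dir == 1) group_a else group_b
    ga <- if (dir == 1) group_b else group_a
    ic <- .charged_atom_rows(a, "cation")
    ic <- ic[a$chain[ic] %in% gc]
    ia <- .charged_atom_rows(a, "anion")
    ia <- ia[a$chain[ia] %in% ga]
    if (length(ic) == 0 || length(ia) == 0) next
    xyzc <- as.matrix(a[ic, c("x", "y", "z")])
    xyza <- as.matrix(a[ia, c("x", "y", "z")])
    pairs <- .grid_neighbor_pairs(xyzc, xyza, cutoff)
    if (nrow(pairs) == 0) next
    i <- ic[pairs[, 1]]; j <- ia[pairs[, 2]]
    d <- sqrt(rowSums((as.matrix(a[i, c("x", "y", "z")]) -
                       as.matrix(a[j, c("x", "y", "z")]))^2))
    df <- data.frame(
      cat_chain = a$chain[i], cat_resid = a$resid[i],
      cat_icode = a$icode[i], cat_resname = a$resname[i],
      cat_atom = a$name[i],
      ani_chain = a$chain[j], ani_resid = a$resid[j],
      ani_icode = a$icode[j], ani_resname = a$resname[j],
      ani_atom = a$name[j], distance = d,
      stringsAsFactors = FALSE
    )
    rows[[dir]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    ## residue-pair deduplication: keep the minimal-distance atom pair
    key <- paste(out$cat_chain, out$cat_resid, out$cat_icode,
                 out$ani_chain, out$ani_resid, out$ani_icode)
    out <- out[order(key, out$distance), , drop = FALSE]
    out <- out[!duplicated(paste(out$cat_chain, out$cat_resid,
                                 out$cat_icode, out$ani_chain,
                                 out$ani_resid, out$ani_icode)), ,
               drop = FALSE]
    out <- out[order(out$cat_chain, out$cat_resid, out$cat_icode,
                     out$ani_chain, out$ani_resid, out$ani_icode), ,
               drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- empty
  }
  class(out) <- c("yrb_salt_bridges", "data.frame")
  out
}

## subset model to a set of chains
subset_chains <- function(model, chains) {
  m <- model
  m$atoms <- m$atoms[m$atoms$chain %in% chains, , drop = FALSE]
  rownames(m$atoms) <- NULL
  m
}

#' Detect interface atoms and buried area between two chain groups
#'
#' Buried areas are computed by the delta-SASA definition: an atom's
#' buried area is its solvent-accessible area in its own group alone
#' minus its area in the complex of both groups; interface atoms are
#' those with positive burial (`method = "delta-sasa"`) or, with
#' `method = "distance"`, those with any opposite-group heavy atom
#' within `distance_cutoff`.
#'
#' @param model a hydrogen-free [yrb_structure()].
#' @param group_a,group_b disjoint chain groups (character vectors).
#' @param method interface-atom definition (see above).
#' @param distance_cutoff Angstrom, for `method = "distance"`.
#' @param salt_bridge_cutoff Angstrom, for the included charged-pair scan.
#' @param probe,n_points SASA parameters (see [shrake_rupley_sasa()]).
#' @return an object of class `"yrb_interface"`: list with
#'   `interface_a`/`interface_b` (atom-row indices into `model$atoms`),
#'   `delta_area` (per atom, Angstrom^2), `buried_a`/`buried_b`,
#'   `salt_bridges`, plus the parameters used.
#' @export
interface_atoms <- function(model, group_a, group_b,
                            method = c("delta-sasa", "distance"),
                            distance_cutoff = 5.0,
                            salt_bridge_cutoff = 4.0,
                            probe = 1.4, n_points = 960) {
  method <- match.arg(method)
  stopifnot(inherits(model, "yrb_structure"))
  .check_groups(model, group_a, group_b)
  a <- model$atoms
  in_a <- a$chain %in% group_a
  in_b <- a$chain %in% group_b
  complex <- subset_chains(model, c(group_a, group_b))
  ca <- complex$atoms$chain %in% group_a
  sasa_complex <- shrake_rupley_sasa(complex, probe, n_points)
  sasa_alone_a <- shrake_rupley_sasa(subset_chains(model, group_a),
                                     probe, n_points)
  sasa_alone_b <- shrake_rupley_sasa(subset_chains(model, group_b),
                                     probe, n_points)
  delta <- rep(NA_real_, nrow(a))
  delta[in_a] <- sasa_alone_a$area - sasa_complex$area[ca]
  delta[in_b] <- sasa_alone_b$area - sasa_complex$area[!ca]
  eps <- 1e-9
  if (method == "delta-sasa") {
    iface_a <- which(in_a & delta > eps)
    iface_b <- which(in_b & delta > eps)
  } else {
    xa <- as.matrix(a[in_a, c("x", "y", "z")])
    xb <- as.matrix(a[in_b, c("x", "y", "z")])
    pairs <- .grid_neighbor_pairs(xa, xb, distance_cutoff)
    iface_a <- which(in_a)[sort(unique(pairs[, 1]))]
    iface_b <- which(in_b)[sort(unique(pairs[, 2]))]
  }
  structure(list(
    group_a = group_a, group_b = group_b, method = method,
    interface_a = iface_a, interface_b = iface_b,
    delta_area = delta,
    buried_a = sum(pmax(delta[in_a], 0)),
    buried_b = sum(pmax(delta[in_b], 0)),
    salt_bridges = find_salt_bridges(model, group_a, group_b,
                                     cutoff = salt_bridge_cutoff),
    distance_cutoff = distance_cutoff,
    salt_bridge_cutoff = salt_bridge_cutoff,
    probe = probe, n_points = n_points
  ), class = "yrb_interface")
}

#' @export
print.yrb_interface <- function(x, ...) {
  cat(sprintf(
    "yrb_interface %s vs %s (%s): %d/%d interface atoms, buried %.1f/%.1f A^2, %d salt bridge(s)\n",
    paste(x$group_a, collapse = "+"), paste(x$group_b, collapse = "+"),
    x$method, length(x$interface_a), length(x$interface_b),
    x$buried_a, x$buried_b, nrow(x$salt_bridges)))
  invisible(x)
}

#' Per-class buried-area profile of an interface
#'
#' Splits each side's buried area over the YRB classes.  Fractions are
#' reported as `NA` (undefined) for a side with zero buried area.
#'
#' @param classified a [classify_structure()] result on the same model
#'   the report was computed from.
#' @param report a [interface_atoms()] result.
#' @return data.frame with `side` (`"a"`/`"b"`), `class`, `buried_area`,
#'   `fraction`.
#' @export
interface_class_profile <- function(classified, report) {
  stopifnot(inherits(classified, "yrb_classified"),
            inherits(report, "yrb_interface"))
  a <- classified$model$atoms
  stopifnot(length(report$delta_area) == nrow(a))
  out <- list()
  for (side in c("a", "b")) {
    grp <- if (side == "a") report$group_a else report$group_b
    sel <- a$chain %in% grp
    buried <- pmax(report$delta_area[sel], 0)
    cls <- factor(classified$classes[sel], levels = YRB_CLASSES_ALL)
    per <- vapply(split(buried, cls), sum, numeric(1))
    tot <- sum(per)
    out[[side]] <- data.frame(
      side = side, class = YRB_CLASSES_ALL, buried_area = unname(per),
      fraction = if (tot > 0) unname(per) / tot
                 else rep(NA_real_, length(per)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export an interface report as JSON
#'
#' @param report a [interface_atoms()] result.
#' @param path output path.
#' @param classified optional classification to include the per-class
#'   buried-area profile.
#' @return `path`, invisibly.
#' @export
export_interface_report <- function(report, path, classified = NULL) {
  payload <- list(
    group_a = report$group_a, group_b = report$group_b,
    method = report$method,
    n_interface_atoms = c(a = length(report$interface_a),
                          b = length(report$interface_b)),
    buried_area = c(a = report$buried_a, b = report$buried_b),
    salt_bridge_cutoff = report$salt_bridge_cutoff,
    n_salt_bridges = nrow(report$salt_bridges),
    salt_bridges = as.data.frame(report$salt_bridges)
  )
  if (!is.null(classified))
    payload$class_profile <- interface_class_profile(classified, report)
  jsonlite::write_json(payload, path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write salt bridges as a TSV table
#'
#' @param bridges a [find_salt_bridges()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_salt_bridges_tsv <- function(bridges, path) {
  utils::write.table(as.data.frame(bridges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write salt bridges as a PyMOL distance-object script
#'
#' Each bridge becomes a `distance` command between its two charged
#' atoms, for visual checking in a molecular viewer.
#'
#' @param bridges a [find_salt_bridges()] result.
#' @param object_name PyMOL object name the selections refer to.
#' @return character vector of script lines.
#' @export
salt_bridge_pymol_script <- function(bridges, object_name = "structure") {
  b <- as.data.frame(bridges)
  if (nrow(b) == 0) return(character(0))
  vapply(seq_len(nrow(b)), function(i) {
    sprintf("distance sb%d, %s//%s/%s%s/%s, %s//%s/%s%s/%s",
            i, object_name,
            b$cat_chain[i], b$cat_resid[i], b$cat_icode[i], b$cat_atom[i],
            object_name,
            b$ani_chain[i], b$ani_resid[i], b$ani_icode[i], b$ani_atom[i])
  }, character(1))
}
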