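## Structure input/output: a flat atom-table model of a macromolecular
## structure (one coordinate model, altlocs resolved), read from PDB or
## mmCIF via bio3d, written back as fixed-column PDB.

#' Construct a structure model from an atom table
#'
#' The model is a thin S3 wrapper around a data.frame of heavy-atom (and
#' possibly hydrogen) records with one row per atom, ordered as in the
#' source.  Columns: `serial`, `name`, `altloc`, `resname`, `chain`,
#' `resid`, `icode`, `x`, `y`, `z`, `occupancy`, `b_factor`, `element`,
#' `is_hetero`.
#'
#' @param atoms data.frame as described above; missing `serial`,
#'   `altloc`, `icode`, `occupancy`, `b_factor`, `is_hetero` and
#'   `element` columns are filled with defaults (elements inferred from
#'   atom names).
#' @param id identifier string (e.g. a PDB code or file stem).
#' @param source_format `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @return an object of class `"yrb_structure"`.
#' @export
yrb_structure <- function(atoms, id = "model", source_format = "synthetic") {
  stopifnot(is.data.frame(atoms))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- rep("", n)
  if (is.null(atoms$icode)) atoms$icode <- rep("", n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$b_factor)) atoms$b_factor <- rep(0, n)
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- rep(FALSE, n)
  if (is.null(atoms$element) || any(!nzchar(atoms$element))) {
    inferred <- infer_element(atoms$name, atoms$resname)
    if (is.null(atoms$element)) {
      atoms$element <- inferred
    } else {
      blank <- !nzchar(atoms$element)
      atoms$element[blank] <- inferred[blank]
    }
  }
  atoms$element <- normalize_element(atoms$element)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  req <- c("serial", "name", "altloc", "resname", "chain", "resid",
           "icode", "x", "y", "z", "occupancy", "b_factor", "element",
           "is_hetero")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, req]
  rownames(atoms) <- NULL
  if (n > 0) {
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("non-finite atom coordinates")
    occ <- atoms$occupancy
    if (any(!is.na(occ) & (occ < 0 | occ > 1)))
      stop("occupancy outside [0, 1]")
    if (any(!nzchar(atoms$element)))
      stop("empty element symbol after normalization")
  }
  structure(list(id = id, source_format = source_format, atoms = atoms),
            class = "yrb_structure")
}

#' @export
print.yrb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("yrb_structure '%s' (%s): %d atoms, %d chains, %d residues\n",
              x$id, x$source_format, nrow(a),
              length(unique(a$chain)),
              nrow(unique(a[, c("chain", "resid", "icode")]))))
  invisible(x)
}

#' @export
as.data.frame.yrb_structure <- function(x, ...) x$atoms

#' Number of atoms in a structure model
#' @param model a `yrb_structure`.
#' @return integer atom count.
#' @export
natoms <- function(model) nrow(model$atoms)

## Unique residue key strings "chain|resid|icode" aligned with atom rows.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resid, atoms$icode, sep = "|")
}

## Table of distinct residues in model order.
residue_table <- function(model) {
  a <- model$atoms
  keep <- !duplicated(residue_key(a))
  out <- a[keep, c("chain", "resid", "icode", "resname")]
  rownames(out) <- NULL
  out
}

## n x 3 coordinate matrix.
coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(sub("\\.gz$", "", path))))
    writeLines(readLines(gzfile(path)), tmp)
    tmp
  } else {
    path
  }
}

#' Read a PDB or mmCIF file into a structure model
#'
#' Parses the file (transparently decompressing `.gz`), keeps the first
#' coordinate model only, resolves alternate locations to the highest
#' occupancy variant (ties broken by file order), and populates element
#' symbols (inferred from atom names when the element column is absent).
#' Hydrogens are retained; call [strip_hydrogens()] to remove them.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file, optionally
#'   gzipped.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (extension-based).
#' @return a [yrb_structure()].
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_pdb(build_peptide("AR", chain = "A"), pdb)
#' read_structure(pdb)
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      stop("cannot determine format from extension '", ext,
           "'; pass format = 'pdb' or 'mmcif'"))
  }
  local_path <- .open_maybe_gz(path)
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(local_path, multi = FALSE,
                                         rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(local_path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty structure: no atom records in '", path, "'")
  n <- nrow(at)
  elesy <- if (!is.null(at$elesy)) trimws(at$elesy) else rep("", n)
  elesy[is.na(elesy)] <- ""
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resid = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    element = elesy,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altlocs(atoms)
  id <- sub("\\.gz$", "", basename(path))
  id <- tools::file_path_sans_ext(id)
  yrb_structure(atoms, id = id, source_format = format)
}

## Keep, per (residue, atom name), the highest-occupancy alternate
## location; ties and the altloc-blank record fall back to file order.
resolve_altlocs <- function(atoms) {
  key <- paste(residue_key(atoms), atoms$resname, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
  ## stable order: by descending occupancy within key, file order on ties
  ord <- order(key, -occ, seq_len(nrow(atoms)))
  keep_first <- !duplicated(key[ord])
  sel <- sort(ord[keep_first])
  atoms <- atoms[sel, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Remove hydrogen (and deuterium) atoms
#'
#' Idempotent: atoms whose element is `H` or `D` are dropped, everything
#' else is preserved in order.  Atom-name based element inference has
#' already happened at read time, so digit-prefixed hydrogen names
#' (`"1HG1"`) in element-less files are removed too.
#'
#' @param model a [yrb_structure()].
#' @return the model without hydrogens.
#' @export
strip_hydrogens <- function(model) {
  stopifnot(inherits(model, "yrb_structure"))
  keep <- !(model$atoms$element %in% c("H", "D"))
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Write a structure model as a PDB file
#'
#' Emits standard fixed-column PDB records (via bio3d).  Coordinates are
#' written to 3 decimals and B-factors to 2, so a read/write round trip
#' reproduces them at that precision.
#'
#' @param model a [yrb_structure()].
#' @param path output file path.
#' @param b_factor_override optional numeric vector of replacement
#'   B-factors, either full length (one per atom) or named by atom serial
#'   numbers for a subset.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, b_factor_override = NULL) {
  stopifnot(inherits(model, "yrb_structure"))
  a <- model$atoms
  if (any(nchar(a$chain) > 1))
    stop("chain id(s) too long for PDB format: ",
         paste(unique(a$chain[nchar(a$chain) > 1]), collapse = ", "))
  b <- a$b_factor
  if (!is.null(b_factor_override)) {
    if (is.null(names(b_factor_override))) {
      if (length(b_factor_override) != nrow(a))
        stop("unnamed b_factor_override must have one value per atom")
      b <- as.numeric(b_factor_override)
    } else {
      idx <- match(as.integer(names(b_factor_override)), a$serial)
      if (anyNA(idx))
        stop("b_factor_override names not matching atom serials: ",
             paste(names(b_factor_override)[is.na(idx)], collapse = ", "))
      b[idx] <- as.numeric(b_factor_override)
    }
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resid, resid = a$resname,
    eleno = a$serial, elety = a$name,
    chain = ifelse(nzchar(a$chain), a$chain, " "),
    insert = ifelse(nzchar(a$icode), a$icode, ""),
    alt = ifelse(nzchar(a$altloc), a$altloc, ""),
    o = a$occupancy, b = b,
    elesy = a$element
  )
  invisible(path)
}
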