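## Deterministic synthetic fixtures: idealized residues, extended
## peptides, and two-chain "planted dimer" models whose inter-chain
## charged contacts are placed at prescribed distances.  Fixtures test
## classification and geometry, not conformational realism: peptides are
## built in an extended conformation (phi = psi = omega = 180 degrees).

## backbone geometry constants (Angstrom / degrees)
.BB <- list(
  n_ca = 1.46, ca_c = 1.52, c_o = 1.23, c_oxt = 1.25, c_n = 1.33,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5
)

## Realize one residue given the previous residue's backbone anchors
## (NULL for the chain start).  Returns list(atoms = data.frame, anchors).
.realize_residue <- function(code, prev = NULL, phi = 180, psi = 180,
                             omega = 180) {
  tpl <- RESIDUE_TEMPLATES[[code]]
  if (is.null(tpl)) stop("no residue template for code '", code, "'")
  pos <- list()
  if (is.null(prev)) {
    pos$N <- c(0, 0, 0)
    pos$CA <- c(.BB$n_ca, 0, 0)
    pos$C <- place_atom(c(0, 1, 0), pos$N, pos$CA,
                        .BB$ca_c, .BB$ang_n_ca_c, 0)
  } else {
    pos$N <- place_atom(prev$N, prev$CA, prev$C,
                        .BB$c_n, .BB$ang_ca_c_n, psi)
    pos$CA <- place_atom(prev$CA, prev$C, pos$N,
                         .BB$n_ca, .BB$ang_c_n_ca, omega)
    pos$C <- place_atom(prev$C, pos$N, pos$CA,
                        .BB$ca_c, .BB$ang_n_ca_c, phi)
  }
  ## carbonyl O anti to the following amide nitrogen (psi + 180)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, .BB$c_o, .BB$ang_ca_c_o,
                      (psi + 180) %% 360)
  if (!is.null(tpl$sc)) {
    for (i in seq_len(nrow(tpl$sc))) {
      row <- tpl$sc[i, ]
      pos[[row$name]] <- place_atom(pos[[row$r]], pos[[row$q]],
                                    pos[[row$p]], row$b, row$ang, row$dih)
    }
  }
  nm <- names(pos)
  elem <- c(N = "N", CA = "C", C = "C", O = "O")[nm]
  if (!is.null(tpl$sc)) {
    sc_elem <- setNames(tpl$sc$elem, tpl$sc$name)
    elem[is.na(elem)] <- sc_elem[nm[is.na(elem)]]
  }
  xyz <- do.call(rbind, pos)
  list(
    atoms = data.frame(name = nm, element = unname(elem),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    anchors = pos[c("N", "CA", "C")]
  )
}

#' Build one idealized residue
#'
#' Realizes the heavy atoms of a templated residue in 3-D from its
#' internal coordinates.  Distance-based bond inference on the result
#' reproduces the template's reference bond list.
#'
#' @param code three-letter residue code with a template
#'   (see [list_residue_templates()]).
#' @return list with `code` and `atoms` (data.frame: `name`, `element`,
#'   `x`, `y`, `z`); no OXT (that belongs to a chain terminus).
#' @export
#' @examples
#' build_residue("ARG")$atoms$name
build_residue <- function(code) {
  code <- toupper(code)
  r <- .realize_residue(code)
  list(code = code, atoms = r$atoms)
}

## accept "ADE..." one-letter strings or c("ALA","ASP",...) vectors
.parse_sequence <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% names(RESIDUE_TEMPLATES) &&
      nchar(sequence) >= 1) {
    codes <- unname(ONE_TO_THREE[strsplit(toupper(sequence), "")[[1]]])
    if (anyNA(codes)) stop("unknown one-letter code(s) in sequence '",
                           sequence, "'")
    codes
  } else {
    toupper(sequence)
  }
}

#' Build an extended peptide chain
#'
#' Consecutive residues are joined by ideal peptide bonds
#' (C-N = 1.33 Angstrom) in an extended conformation; the C-terminal
#' residue carries an OXT.  The result is clash-free (no non-bonded
#' contact below 2 Angstrom).
#'
#' @param sequence residue sequence: a one-letter string (`"ADE"`) or a
#'   vector of three-letter codes.
#' @param chain chain identifier (single character).
#' @param resid_start first residue number.
#' @param id model identifier.
#' @return a [yrb_structure()] with a single chain.
#' @export
#' @examples
#' build_peptide("ACDEFGHIKLMNPQRSTVWY")
build_peptide <- function(sequence, chain = "A", resid_start = 1,
                          id = "peptide") {
  codes <- .parse_sequence(sequence)
  if (length(codes) == 0) stop("empty sequence")
  prev <- NULL
  rows <- vector("list", length(codes))
  for (i in seq_along(codes)) {
    ## proline cannot adopt phi = 180 (its ring closes through the backbone
    ## nitrogen); use its sterically allowed phi instead
    phi <- if (codes[i] == "PRO") -70 else 180
    r <- .realize_residue(codes[i], prev = prev, phi = phi)
    at <- r$atoms
    if (i == length(codes)) {
      oxt <- place_atom(r$anchors$N, r$anchors$CA, r$anchors$C,
                        .BB$c_oxt, .BB$ang_ca_c_o, 180)
      at <- rbind(at, data.frame(name = "OXT", element = "O",
                                 x = oxt[1], y = oxt[2], z = oxt[3]))
    }
    at$resname <- codes[i]
    at$resid <- resid_start + i - 1
    rows[[i]] <- at
    prev <- r$anchors
  }
  atoms <- do.call(rbind, rows)
  atoms$chain <- chain
  yrb_structure(atoms, id = id, source_format = "synthetic")
}

## merge two single-chain models into one
.merge_models <- function(a, b, id) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  yrb_structure(atoms, id = id, source_format = "synthetic")
}

## evaluation-state RNG hygiene: run expr with a local seed, restoring
## the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a two-chain dimer with planted inter-chain contacts
#'
#' Two extended peptides are placed as rigid bodies so that each requested
#' atom pair across the chains sits at its target distance (within
#' 0.05 Angstrom) while no inter-chain non-bonded contact falls below
#' 2 Angstrom.  Placement is found by seeded random restarts of a
#' rigid-body least-squares fit, so results are deterministic per seed.
#'
#' @param seq_a,seq_b sequences of the two chains (as in
#'   [build_peptide()]); chains are labelled `"A"` and `"B"`.
#' @param contacts list of planted contacts; each element is a list with
#'   `res_a`, `atom_a`, `res_b`, `atom_b`, `distance` -- residue numbers
#'   refer to position in the chain (starting at 1).
#' @param seed integer seed for the placement search.
#' @param max_restarts random restarts before giving up.
#' @return a [yrb_structure()] with chains A and B; attribute
#'   `"planted_contacts"` records the achieved distances.
#' @export
#' @examples
#' dim <- build_planted_dimer("GKG", "GDG",
#'   contacts = list(list(res_a = 2, atom_a = "NZ",
#'                        res_b = 2, atom_b = "OD1", distance = 3.5)))
#' attr(dim, "planted_contacts")
build_planted_dimer <- function(seq_a, seq_b, contacts, seed = 1,
                                max_restarts = 40) {
  stopifnot(length(contacts) >= 1)
  pa <- build_peptide(seq_a, chain = "A", id = "dimerA")
  pb <- build_peptide(seq_b, chain = "B", id = "dimerB")
  xa <- coords(pa)
  xb0 <- coords(pb)
  ia <- vapply(contacts, function(ct) {
    i <- which(pa$atoms$resid == ct$res_a & pa$atoms$name == ct$atom_a)
    if (length(i) != 1) stop("contact atom ", ct$atom_a, " not found in chain A residue ", ct$res_a)
    i
  }, integer(1))
  ib <- vapply(contacts, function(ct) {
    i <- which(pb$atoms$resid == ct$res_b & pb$atoms$name == ct$atom_b)
    if (length(i) != 1) stop("contact atom ", ct$atom_b, " not found in chain B residue ", ct$res_b)
    i
  }, integer(1))
  targets <- vapply(contacts, function(ct) ct$distance, numeric(1))
  stopifnot(all(targets > 0))

  transform_b <- function(par) {
    R <- rotation_matrix(c(1, 0, 0), par[1]) %*%
      rotation_matrix(c(0, 1, 0), par[2]) %*%
      rotation_matrix(c(0, 0, 1), par[3])
    ctr <- colMeans(xb0)
    sweep(t(R %*% t(sweep(xb0, 2, ctr))), 2, -par[4:6] - ctr, "-")
  }
  objective <- function(par) {
    xb <- transform_b(par)
    d <- sqrt(rowSums((xa[ia, , drop = FALSE] - xb[ib, , drop = FALSE])^2))
    dall <- cross_distances(xa, xb)
    clash <- pmax(0, 2.0 - dall)
    100 * sum((d - targets)^2) + sum(clash^2)
  }

  .with_seed(seed, {
    for (trial in seq_len(max_restarts)) {
      u <- unit(stats::rnorm(3))
      par0 <- c(stats::runif(3, -pi, pi),
                colMeans(xa) + u * (max(targets) + 6) - colMeans(xb0))
      fit <- stats::optim(par0, objective, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      xb <- transform_b(fit$par)
      d <- sqrt(rowSums((xa[ia, , drop = FALSE] - xb[ib, , drop = FALSE])^2))
      dmin <- min(cross_distances(xa, xb))
      if (max(abs(d - targets)) <= 0.05 && dmin >= 2.0 - 1e-9) {
        pb$atoms$x <- xb[, 1]; pb$atoms$y <- xb[, 2]; pb$atoms$z <- xb[, 3]
        out <- .merge_models(pa, pb, id = "planted_dimer")
        attr(out, "planted_contacts") <- data.frame(
          res_a = vapply(contacts, `[[`, numeric(1), "res_a"),
          atom_a = vapply(contacts, `[[`, character(1), "atom_a"),
          res_b = vapply(contacts, `[[`, numeric(1), "res_b"),
          atom_b = vapply(contacts, `[[`, character(1), "atom_b"),
          target = targets, achieved = d
        )
        return(out)
      }
    }
    stop("could not satisfy planted contacts within 0.05 Angstrom ",
         "after ", max_restarts, " restarts (unsatisfiable spec?)")
  })
}

#' Write the package's standard fixture set to a directory
#'
#' Emits a small collection of synthetic PDB files used throughout the
#' documentation and tests: a single alanine, a 20-mer containing each
#' standard amino acid once, and a planted salt-bridge dimer.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the dimer placement.
#' @return character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ala = file.path(dir, "ala.pdb"),
    all20 = file.path(dir, "all20.pdb"),
    dimer = file.path(dir, "salt_bridge_dimer.pdb")
  )
  write_pdb(build_peptide("A", id = "ala"), paths["ala"])
  write_pdb(build_peptide("ACDEFGHIKLMNPQRSTVWY", id = "all20"),
            paths["all20"])
  dimer <- build_planted_dimer("GKG", "GDG",
    contacts = list(list(res_a = 2, atom_a = "NZ",
                         res_b = 2, atom_b = "OD1", distance = 3.5)),
    seed = seed)
  write_pdb(dimer, paths["dimer"])
  invisible(paths)
}
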