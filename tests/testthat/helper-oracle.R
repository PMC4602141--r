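# Hand-derived YRB classification of every heavy atom of the 20 standard
# amino acids, written out independently of the package's table builder:
# for each side chain the carbons bonded to N or O were identified from
# textbook residue connectivity by hand, charged groups are the Asp/Glu
# carboxylates and Lys/Arg amine/guanidinium, and everything else
# (including the backbone and OXT) is neutral.

hand_derived_table <- local({
  bb <- c(N = "neutral", CA = "neutral", C = "neutral", O = "neutral",
          OXT = "neutral")
  side <- list(
    ALA = c(CB = "hydrophobic"),
    ARG = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            NE = "positive", CZ = "neutral", NH1 = "positive",
            NH2 = "positive"),
    ASN = c(CB = "hydrophobic", CG = "neutral", OD1 = "neutral",
            ND2 = "neutral"),
    ASP = c(CB = "hydrophobic", CG = "neutral", OD1 = "negative",
            OD2 = "negative"),
    CYS = c(CB = "hydrophobic", SG = "neutral"),
    GLN = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            OE1 = "neutral", NE2 = "neutral"),
    GLU = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
            OE1 = "negative", OE2 = "negative"),
    GLY = c(),
    HIS = c(CB = "hydrophobic", CG = "neutral", ND1 = "neutral",
            CD2 = "neutral", CE1 = "neutral", NE2 = "neutral"),
    ILE = c(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic",
            CD1 = "hydrophobic"),
    LEU = c(CB = "hydrophobic", CG = "hydrophobic", CD1 = "hydrophobic",
            CD2 = "hydrophobic"),
    LYS = c(CB = "hydrophobic", CG = "hydrophobic", CD = "hydrophobic",
            CE = "neutral", NZ = "positive"),
    MET = c(CB = "hydrophobic", CG = "hydrophobic", SD = "neutral",
            CE = "hydrophobic"),
    PHE = c(CB = "hydrophobic", CG = "hydrophobic", CD1 = "hydrophobic",
            CD2 = "hydrophobic", CE1 = "hydrophobic", CE2 = "hydrophobic",
            CZ = "hydrophobic"),
    PRO = c(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral"),
    SER = c(CB = "neutral", OG = "neutral"),
    THR = c(CB = "neutral", OG1 = "neutral", CG2 = "hydrophobic"),
    TRP = c(CB = "hydrophobic", CG = "hydrophobic", CD1 = "neutral",
            CD2 = "hydrophobic", NE1 = "neutral", CE2 = "neutral",
            CE3 = "hydrophobic", CZ2 = "hydrophobic", CZ3 = "hydrophobic",
            CH2 = "hydrophobic"),
    TYR = c(CB = "hydrophobic", CG = "hydrophobic", CD1 = "hydrophobic",
            CD2 = "hydrophobic", CE1 = "hydrophobic", CE2 = "hydrophobic",
            CZ = "neutral", OH = "neutral"),
    VAL = c(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic")
  )
  rows <- lapply(names(side), function(res) {
    cls <- c(bb, side[[res]])
    data.frame(resname = res, atom = names(cls), class = unname(cls),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
})

# canonical string form of an undirected bond set
canonical_bonds <- function(bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) return(character(0))
  sort(apply(bonds, 1, function(r) paste(sort(r), collapse = "-")))
}

# brute-force O(n^2) salt-bridge scan used as the independent oracle
# against the grid-based neighbor search
all_pairs_salt_bridges <- function(model, group_a, group_b, cutoff = 4.0) {
  a <- model$atoms
  cation_spec <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  anion_spec <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  pick <- function(spec, chains) {
    hits <- integer(0)
    for (res in names(spec))
      hits <- c(hits, which(a$resname == res & a$name %in% spec[[res]] &
                            a$chain %in% chains))
    sort(hits)
  }
  found <- list()
  for (dir in 1:2) {
    gc <- if (dir == 1) group_a else group_b
    ga <- if (dir == 1) group_b else group_a
    for (i in pick(cation_spec, gc)) {
      for (j in pick(anion_spec, ga)) {
        d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
        if (d <= cutoff) {
          key <- paste(a$chain[i], a$resid[i], a$icode[i],
                       a$chain[j], a$resid[j], a$icode[j])
          if (is.null(found[[key]]) || d < found[[key]]$distance) {
            found[[key]] <- list(
              cat_chain = a$chain[i], cat_resid = a$resid[i],
              cat_atom = a$name[i],
              ani_chain = a$chain[j], ani_resid = a$resid[j],
              ani_atom = a$name[j], distance = d)
          }
        }
      }
    }
  }
  if (length(found) == 0)
    return(data.frame(cat_chain = character(0), cat_resid = integer(0),
                      cat_atom = character(0), ani_chain = character(0),
                      ani_resid = integer(0), ani_atom = character(0),
                      distance = numeric(0)))
  out <- do.call(rbind, lapply(found, as.data.frame))
  out <- out[order(out$cat_chain, out$cat_resid, out$ani_chain,
                   out$ani_resid), ]
  rownames(out) <- NULL
  out
}

# minimal fixed-column PDB text for hand-crafted parsing fixtures
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1, b = 0, element = "", altloc = " ",
                          icode = " ") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, altloc, resname, chain, resid, icode,
          x, y, z, occ, b, element)
}

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
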