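planted <- function(dist, seed = 3, seq_a = "GKG", seq_b = "GDG",
                    atom_a = "NZ", atom_b = "OD1") {
  build_planted_dimer(seq_a, seq_b,
    contacts = list(list(res_a = 2, atom_a = atom_a, res_b = 2,
                         atom_b = atom_b, distance = dist)),
    seed = seed)
}

# minimal two-chain model with the charged atoms at exact distances:
# LYS NZ at the origin, ASP OD1/OD2 on the x axis
charged_pair_model <- function(d_od1, d_od2 = d_od1 + 0.4) {
  yrb_structure(data.frame(
    name = c("NZ", "OD1", "OD2"),
    resname = c("LYS", "ASP", "ASP"),
    chain = c("A", "B", "B"), resid = c(1, 1, 1),
    x = c(0, d_od1, d_od2), y = 0, z = 0,
    element = c("N", "O", "O"), is_hetero = FALSE,
    stringsAsFactors = FALSE))
}

test_that("planted salt bridges are recovered at their planted distance", {
  m <- planted(3.5)
  b <- find_salt_bridges(m, "A", "B")
  expect_equal(nrow(b), 1)
  expect_equal(b$cat_resname, "LYS")
  expect_equal(b$cat_atom, "NZ")
  expect_equal(b$ani_resname, "ASP")
  ## the reported pair is the minimal-distance carboxylate oxygen, so it
  ## can only be at or below the planted 3.5 Angstrom
  expect_true(b$ani_atom %in% c("OD1", "OD2"))
  expect_lte(b$distance, 3.5 + 0.05)
  expect_gte(b$distance, 2.0)
})

test_that("the distance criterion is an exact threshold", {
  ## both oxygens beyond 4.0: nothing at the default cutoff
  expect_equal(nrow(find_salt_bridges(charged_pair_model(4.5), "A", "B")), 0)
  expect_equal(nrow(find_salt_bridges(charged_pair_model(6.0), "A", "B")), 0)
  ## a wider cutoff recovers the pair, reporting the closer oxygen
  b <- find_salt_bridges(charged_pair_model(4.5), "A", "B", cutoff = 5.0)
  expect_equal(nrow(b), 1)
  expect_equal(b$ani_atom, "OD1")
  expect_equal(b$distance, 4.5)
  ## boundary: a pair exactly at the cutoff counts
  expect_equal(nrow(find_salt_bridges(charged_pair_model(4.0), "A", "B")), 1)
  expect_equal(nrow(find_salt_bridges(charged_pair_model(4.0 + 1e-6),
                                      "A", "B")), 0)
  ## empty model
  empty <- yrb_structure(data.frame(
    name = c("CA", "CA"), resname = "GLY", chain = c("A", "B"),
    resid = 1, x = c(0, 50), y = 0, z = 0, element = "C",
    is_hetero = FALSE))
  expect_equal(nrow(find_salt_bridges(empty, "A", "B")), 0)
})

test_that("salt-bridge search is symmetric and residue-deduplicated", {
  ## arginine's three guanidinium nitrogens against a glutamate: one pair
  m <- planted(3.8, seq_a = "GRG", seq_b = "GEG",
               atom_a = "NH1", atom_b = "OE1")
  b <- find_salt_bridges(m, "A", "B")
  expect_equal(nrow(b), 1)
  swapped <- find_salt_bridges(m, "B", "A")
  expect_equal(nrow(swapped), 1)
  expect_equal(b$distance, swapped$distance)
  expect_equal(b$cat_chain, swapped$cat_chain)  # cation stays the cation
})

test_that("histidine is never a salt-bridge donor", {
  m <- planted(3.5, seq_a = "GHG", seq_b = "GDG",
               atom_a = "NE2", atom_b = "OD1")
  expect_equal(nrow(find_salt_bridges(m, "A", "B")), 0)
})

test_that("neighbor search equals the all-pairs oracle on random dimers", {
  cases <- list(
    list(seq_a = "KDKEK", seq_b = "DEKDE", d = 3.2, aa = "NZ", ab = "OD1",
         ra = 1, rb = 1),
    list(seq_a = "RKRD", seq_b = "EDED", d = 3.9, aa = "NH2", ab = "OD2",
         ra = 3, rb = 2),
    list(seq_a = "GKDG", seq_b = "GEKG", d = 3.6, aa = "NZ", ab = "OE1",
         ra = 2, rb = 2)
  )
  for (seed in 1:3) {
    for (cs in cases) {
      m <- build_planted_dimer(cs$seq_a, cs$seq_b,
        contacts = list(list(res_a = cs$ra, atom_a = cs$aa,
                             res_b = cs$rb, atom_b = cs$ab,
                             distance = cs$d)),
        seed = seed)
      for (cutoff in c(3.0, 4.0, 6.0, 10.0)) {
        got <- find_salt_bridges(m, "A", "B", cutoff = cutoff)
        ref <- all_pairs_salt_bridges(m, "A", "B", cutoff = cutoff)
        expect_equal(nrow(got), nrow(ref),
                     info = sprintf("seed %d cutoff %.1f", seed, cutoff))
        if (nrow(got)) {
          expect_equal(paste(got$cat_chain, got$cat_resid, got$cat_atom,
                             got$ani_chain, got$ani_resid, got$ani_atom),
                       paste(ref$cat_chain, ref$cat_resid, ref$cat_atom,
                             ref$ani_chain, ref$ani_resid, ref$ani_atom))
          expect_equal(got$distance, ref$distance, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("salt bridges are monotone in the cutoff", {
  m <- build_planted_dimer("KDKEK", "DEKDE",
    contacts = list(list(res_a = 1, atom_a = "NZ", res_b = 1,
                         atom_b = "OD1", distance = 3.4)),
    seed = 5)
  key <- function(b) paste(b$cat_chain, b$cat_resid, b$ani_chain,
                           b$ani_resid)
  previous <- character(0)
  for (cutoff in c(2.5, 3.5, 4.5, 6.0, 9.0)) {
    b <- find_salt_bridges(m, "A", "B", cutoff = cutoff)
    expect_true(all(previous %in% key(b)),
                info = sprintf("cutoff %.1f", cutoff))
    expect_true(all(b$distance <= cutoff))
    previous <- key(b)
  }
})

test_that("group validation rejects bad chain groups", {
  m <- planted(3.5)
  expect_error(find_salt_bridges(m, "A", "A"), "overlap")
  expect_error(find_salt_bridges(m, "A", "Z"), "unknown chain")
  expect_error(find_salt_bridges(m, character(0), "B"), "non-empty")
  expect_error(interface_atoms(m, c("A", "B"), "B"), "overlap")
})

test_that("distant chains give an empty interface", {
  a <- build_peptide("ALA", chain = "A")
  b <- build_peptide("GLY", chain = "B")
  b$atoms$x <- b$atoms$x + 100
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  m <- yrb_structure(atoms)
  rep <- interface_atoms(m, "A", "B", n_points = 240)
  expect_length(rep$interface_a, 0)
  expect_length(rep$interface_b, 0)
  expect_equal(rep$buried_a, 0)
  expect_equal(rep$buried_b, 0)
  expect_equal(nrow(rep$salt_bridges), 0)
})

test_that("the distance method flags exactly the proximal residues", {
  m <- planted(3.5, seed = 7)
  rep <- interface_atoms(m, "A", "B", method = "distance",
                         distance_cutoff = 5.0, n_points = 120)
  a <- m$atoms
  ## the planted contact atoms must be interfacial
  nz <- which(a$chain == "A" & a$name == "NZ")
  od <- which(a$chain == "B" & a$name == "OD1")
  expect_true(nz %in% rep$interface_a)
  expect_true(od %in% rep$interface_b)
  ## and every flagged atom really has an opposite neighbor within cutoff
  xa <- as.matrix(a[a$chain == "A", c("x", "y", "z")])
  xb <- as.matrix(a[a$chain == "B", c("x", "y", "z")])
  d <- yrb:::cross_distances(xa, xb)
  expect_setequal(rep$interface_a,
                  which(a$chain == "A")[apply(d <= 5.0, 1, any)])
  expect_setequal(rep$interface_b,
                  which(a$chain == "B")[apply(d <= 5.0, 2, any)])
})

test_that("delta-SASA burial is roughly symmetric on planted dimers", {
  m <- planted(3.2, seed = 2)
  rep <- interface_atoms(m, "A", "B", n_points = 480)
  expect_gt(rep$buried_a, 0)
  expect_gt(rep$buried_b, 0)
  expect_lt(abs(rep$buried_a - rep$buried_b) /
            max(rep$buried_a, rep$buried_b), 0.25)
})

test_that("class profiles sum to one and flag hydrophobic interfaces", {
  ## leucine-only contact: side-chain carbons planted together
  m <- build_planted_dimer("GLG", "GLG",
    contacts = list(list(res_a = 2, atom_a = "CD1", res_b = 2,
                         atom_b = "CD1", distance = 4.0)),
    seed = 4)
  cl <- classify_structure(m)
  rep <- interface_atoms(m, "A", "B", n_points = 480)
  prof <- interface_class_profile(cl, rep)
  for (side in c("a", "b")) {
    rows <- prof[prof$side == side, ]
    expect_equal(sum(rows$fraction), 1, tolerance = 1e-9)
    expect_gt(rows$fraction[rows$class == "hydrophobic"], 0.5)
  }
  ## zero-contact dimer: fractions are undefined (NA), not NaN noise
  far <- planted(3.5)
  far$atoms$x[far$atoms$chain == "B"] <-
    far$atoms$x[far$atoms$chain == "B"] + 500
  rep0 <- interface_atoms(far, "A", "B", n_points = 120)
  prof0 <- interface_class_profile(classify_structure(far), rep0)
  expect_true(all(is.na(prof0$fraction)))
  expect_false(any(is.nan(prof0$fraction)))
})

test_that("interface reports export as JSON and bridges as TSV/PyMOL", {
  m <- planted(3.5)
  cl <- classify_structure(m)
  rep <- interface_atoms(m, "A", "B", n_points = 120)
  fj <- tempfile(fileext = ".json")
  export_interface_report(rep, fj, classified = cl)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$n_salt_bridges, 1)
  expect_equal(j$salt_bridges$cat_atom, "NZ")
  ft <- tempfile(fileext = ".tsv")
  export_salt_bridges_tsv(rep$salt_bridges, ft)
  t <- utils::read.delim(ft)
  expect_equal(nrow(t), 1)
  lines <- salt_bridge_pymol_script(rep$salt_bridges, "dimer")
  expect_length(lines, 1)
  expect_match(lines, "^distance sb1, dimer//A/2/NZ, dimer//B/2/OD[12]$")
})
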