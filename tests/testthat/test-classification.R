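test_that("standard table equals the hand-derived rule application", {
  tab <- build_standard_table()
  key <- function(d) paste(d$resname, d$atom)
  expect_setequal(key(tab), key(hand_derived_table))
  merged <- merge(tab, hand_derived_table, by = c("resname", "atom"))
  expect_equal(nrow(merged), nrow(hand_derived_table))
  mismatch <- merged[merged$class.x != merged$class.y, ]
  expect_equal(nrow(mismatch), 0,
               info = paste(capture.output(print(mismatch)), collapse = "\n"))
})

test_that("table-wide charge and hydrophobicity constraints hold", {
  tab <- build_standard_table()
  elem_of <- function(resname, atom) {
    mapply(function(r, a) {
      topo <- residue_topology(r, terminal = TRUE)
      topo$atoms$elem[topo$atoms$name == a]
    }, resname, atom)
  }
  tab$elem <- elem_of(tab$resname, tab$atom)
  ## hydrophobic is carbon-only
  expect_true(all(tab$elem[tab$class == "hydrophobic"] == "C"))
  ## negative only on Asp/Glu side-chain oxygens
  neg <- tab[tab$class == "negative", ]
  expect_setequal(paste(neg$resname, neg$atom),
                  c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2"))
  ## positive only on Lys/Arg side-chain nitrogens
  pos <- tab[tab$class == "positive", ]
  expect_setequal(paste(pos$resname, pos$atom),
                  c("LYS NZ", "ARG NE", "ARG NH1", "ARG NH2"))
  ## histidine contributes no charged class
  expect_true(all(tab$class[tab$resname == "HIS"] %in%
                  c("hydrophobic", "neutral")))
  ## backbone white everywhere
  bb <- tab[tab$atom %in% c("N", "CA", "C", "O"), ]
  expect_true(all(bb$class == "neutral"))
})

test_that("classify_atom is an exact lookup with unclassified misses", {
  tab <- build_standard_table()
  expect_equal(classify_atom("GLU", "OE1", tab), "negative")
  expect_equal(classify_atom("GLY", "CA", tab), "neutral")
  expect_equal(classify_atom("XYZ", "C1", tab), "unclassified")
  expect_equal(classify_atom("ALA", "ZZ9", tab), "unclassified")
  ## vectorized
  expect_equal(classify_atom(c("ARG", "ARG"), c("CG", "NE"), tab),
               c("hydrophobic", "positive"))
})

test_that("bond inference follows the covalent-radius cutoff", {
  two_c <- function(d) data.frame(
    name = c("C1", "C2"), element = c("C", "C"),
    x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(infer_bonds(two_c(1.54))), 1)
  expect_equal(nrow(infer_bonds(two_c(2.60))), 0)
  ## exact boundary: 2 * 0.76 + 0.45
  expect_equal(nrow(infer_bonds(two_c(1.97))), 1)
  expect_equal(nrow(infer_bonds(two_c(1.98))), 0)
  expect_error(infer_bonds(data.frame(name = "X1", element = "XX",
                                      x = 0, y = 0, z = 0,
                                      stringsAsFactors = FALSE)),
               "X1")
})

test_that("inferred bonds on idealized residues match reference topology", {
  for (code in list_residue_templates(standard_only = TRUE)) {
    res <- build_residue(code)
    expect_identical(canonical_bonds(infer_bonds(res$atoms)),
                     canonical_bonds(residue_topology(code)$bonds),
                     info = code)
  }
})

test_that("a 20-mer classifies atom-for-atom as the table says", {
  p <- build_peptide("ACDEFGHIKLMNPQRSTVWY")
  cl <- classify_structure(p)
  expected <- classify_atom(p$atoms$resname, p$atoms$name)
  expect_identical(cl$classes, expected)
  expect_true(all(cl$provenance == "table"))
  ## deterministic and total
  cl2 <- classify_structure(p)
  expect_identical(cl$classes, cl2$classes)
  expect_false(any(cl$classes == "unclassified"))
})

test_that("bond-inference fallback reproduces table classes for carbons", {
  p <- build_peptide("ACDEFGHIKLMNPQRSTVWY")
  ## force fallback by renaming residues so the table misses them
  q <- p
  q$atoms$resname <- paste0("Z", substr(q$atoms$resname, 1, 2))
  cl_tab <- classify_structure(p)
  cl_inf <- classify_structure(q, fallback = "bond-inference")
  carbons <- p$atoms$element == "C"
  expect_identical(cl_inf$classes[carbons], cl_tab$classes[carbons])
  ## inference never assigns a charge
  expect_true(all(cl_inf$classes %in% c("hydrophobic", "neutral")))
  expect_true(all(cl_inf$provenance == "bond-inference"))
})

test_that("selenomethionine is classified via bond inference", {
  res <- build_residue("MSE")
  at <- res$atoms
  at$resname <- "MSE"; at$resid <- 1; at$chain <- "A"; at$is_hetero <- TRUE
  m <- yrb_structure(at, id = "mse")
  cl <- classify_structure(m, fallback = "bond-inference")
  got <- setNames(cl$classes, m$atoms$name)
  expect_equal(unname(got[c("CB", "CG", "CE")]),
               rep("hydrophobic", 3))   # Se is not N/O
  expect_equal(unname(got["SE"]), "neutral")
  expect_equal(unname(got[c("N", "CA", "C", "O")]), rep("neutral", 4))
})

test_that("hetero compounds and waters default to neutral", {
  atp_like <- data.frame(
    name = c("PA", "O1A", "C5'", "N9", "C8"),
    element = c("P", "O", "C", "N", "C"),
    resname = "ATP", chain = "A", resid = 500,
    x = c(0, 1.5, 3, 4.5, 6), y = 0, z = 0, is_hetero = TRUE)
  wat <- data.frame(name = "O", element = "O", resname = "HOH",
                    chain = "A", resid = 600, x = 10, y = 0, z = 0,
                    is_hetero = TRUE)
  m <- yrb_structure(rbind(atp_like, wat))
  cl <- classify_structure(m)
  expect_true(all(cl$classes == "neutral"))
  expect_true(all(cl$provenance == "policy-default"))
})

test_that("class_composition counts match hand lookups", {
  ## single ALA with OXT: CB hydrophobic, rest neutral
  ala <- build_peptide("A")
  comp <- class_composition(classify_structure(ala))
  expect_equal(comp[["hydrophobic"]], 1)
  expect_equal(comp[["neutral"]], 5)
  expect_equal(sum(comp), natoms(ala))

  ## ARG side chain only: CB,CG yellow; NE,NH1,NH2 blue; CD,CZ white
  arg <- build_residue("ARG")
  side <- arg$atoms[!arg$atoms$name %in% c("N", "CA", "C", "O"), ]
  side$resname <- "ARG"; side$resid <- 1; side$chain <- "A"
  m <- yrb_structure(side)
  comp2 <- class_composition(classify_structure(m, fallback = "skip"))
  expect_equal(comp2[["hydrophobic"]], 2)
  expect_equal(comp2[["positive"]], 3)
  expect_equal(comp2[["neutral"]], 2)

  ## empty model
  empty <- yrb_structure(data.frame(
    name = character(0), resname = character(0), chain = character(0),
    resid = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
    element = character(0), is_hetero = logical(0)))
  expect_true(all(class_composition(classify_structure(empty)) == 0))
})

test_that("charged termini are only marked when asked", {
  p <- build_peptide("GAG")
  cl <- classify_structure(p)
  expect_equal(classify_atom("GLY", "OXT"), "neutral")
  expect_false(any(cl$classes %in% c("positive", "negative")))
  clt <- classify_structure(p, charged_termini = TRUE)
  a <- p$atoms
  expect_equal(clt$classes[a$resid == 1 & a$name == "N"], "positive")
  expect_equal(clt$classes[a$resid == 3 & a$name == "OXT"], "negative")
  expect_equal(clt$classes[a$resid == 3 & a$name == "O"], "negative")
  ## interior backbone unchanged
  expect_equal(clt$classes[a$resid == 2 & a$name == "N"], "neutral")
})

test_that("classification refuses models with hydrogens", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "HA2", "GLY", "A", 1, 1, 0, 0, element = "H")
  )
  m <- read_structure(write_test_pdb(lines))
  expect_error(classify_structure(m), "hydrogens")
})

test_that("classification exports round-trip through JSON and TSV", {
  cl <- classify_structure(build_peptide("RD"))
  fj <- tempfile(fileext = ".json")
  export_classification(cl, fj, format = "json")
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(j), natoms(cl$model))
  expect_equal(j$class, cl$classes)
  ft <- tempfile(fileext = ".tsv")
  export_classification(cl, ft, format = "tsv")
  t <- utils::read.delim(ft, stringsAsFactors = FALSE)
  expect_equal(t$class, cl$classes)
  expect_equal(t$atom, cl$model$atoms$name)
})
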