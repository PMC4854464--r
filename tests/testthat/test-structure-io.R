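# PDB parsing, residue centers, catalytic annotations

test_that("parse_structure reads residues, excludes HETATM, errors on empty", {
  s <- parse_structure(make_pdb(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = list(list("CA", 0, 0, 0), list("CB", 1, 0, 0))),
    list(resid = "ALA", chain = "A", resno = 2,
         atoms = list(list("CA", 4, 0, 0), list("CB", 5, 0, 0)))
  )))
  expect_equal(nrow(s$residues), 2)
  expect_equal(s$chains, "A")
  expect_equal(s$residues$resid, c("ALA", "ALA"))

  het <- paste(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                             record = "HETATM"), "END", sep = "\n")
  expect_error(parse_structure(het), "no standard amino-acid ATOM")
  expect_error(parse_structure("REMARK nothing\nEND"), "no ATOM records")
})

test_that("multi-MODEL assemblies concatenate with renamed chain copies", {
  res <- list(list(resid = "ALA", chain = "A", resno = 1,
                   atoms = list(list("CB", 0, 0, 0))),
              list(resid = "ALA", chain = "A", resno = 2,
                   atoms = list(list("CB", 5, 0, 0))))
  s <- parse_structure(make_pdb(res, models = 2))
  expect_setequal(s$chains, c("A", "A-2"))
  expect_equal(nrow(s$residues), 4)
  # copy 2 is the translated image of copy 1
  expect_equal(s$residues$x[s$residues$chain == "A-2"],
               s$residues$x[s$residues$chain == "A"] + 50)
})

test_that("single_chain mode returns the chain subset of the assembly", {
  res <- list(list(resid = "ALA", chain = "A", resno = 1,
                   atoms = list(list("CB", 0, 0, 0))),
              list(resid = "VAL", chain = "B", resno = 1,
                   atoms = list(list("CB", 8, 0, 0))))
  pdb <- make_pdb(res)
  full <- parse_structure(pdb)
  one <- parse_structure(pdb, mode = "single_chain", chain = "B")
  expect_equal(one$residues,
               full$residues[full$residues$chain == "B", ],
               ignore_attr = TRUE)
  expect_error(parse_structure(pdb, mode = "single_chain", chain = "Z"),
               "lookup error")
})

test_that("altloc keeps the highest-occupancy conformer, ties to file order", {
  lines <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0, occ = 0.3, alt = "A"),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 9, 0, 0, occ = 0.7, alt = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 2, 1, 0, 0, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "CB", "ALA", "A", 2, 8, 0, 0, occ = 0.5, alt = "B"),
    "END")
  s <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$residues$x, c(9, 1))  # 0.7 wins; tie -> first listed
})

test_that("MSE maps to MET; other nonstandard residues drop with a warning", {
  lines <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "SE", "MSE", "A", 2, 3, 0, 0, element = "SE",
                  record = "HETATM"),
    pdb_atom_line(3, "CB", "XYZ", "A", 3, 6, 0, 0),
    "END")
  expect_warning(s <- parse_structure(paste(lines, collapse = "\n")),
                 "XYZ")
  expect_equal(s$residues$resid, c("ALA", "MET"))
})

test_that("residue_center averages side-chain atoms with the glycine CA rule", {
  atoms <- data.frame(elety = c("N", "CA", "CB", "CG"), resid = "LEU",
                      x = c(9, 9, 0, 2), y = c(9, 9, 0, 0),
                      z = c(9, 9, 0, 0), stringsAsFactors = FALSE)
  expect_equal(residue_center(atoms), c(1, 0, 0))

  gly <- data.frame(elety = c("N", "CA"), resid = "GLY",
                    x = c(0, 5), y = c(0, 5), z = c(0, 5),
                    stringsAsFactors = FALSE)
  expect_equal(residue_center(gly), c(5, 5, 5))

  # disordered side chain of a non-glycine falls back to CA with a message
  bare <- data.frame(elety = c("N", "CA"), resid = "SER",
                     x = c(0, 1), y = c(0, 2), z = c(0, 3),
                     stringsAsFactors = FALSE)
  expect_message(ctr <- residue_center(bare), "using CA")
  expect_equal(ctr, c(1, 2, 3))

  no_atoms <- data.frame(elety = character(), resid = character(),
                         x = numeric(), y = numeric(), z = numeric())
  expect_error(residue_center(no_atoms), "no atoms")
})

test_that("residue_center is atom-order invariant and translation equivariant", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    atoms <- data.frame(
      elety = paste0("C", seq_len(n)), resid = "LEU",
      x = rnorm(n), y = rnorm(n), z = rnorm(n), stringsAsFactors = FALSE)
    ctr <- residue_center(atoms)
    expect_equal(residue_center(atoms[sample(n), ]), ctr)
    v <- rnorm(3)
    shifted <- atoms
    shifted$x <- shifted$x + v[1]
    shifted$y <- shifted$y + v[2]
    shifted$z <- shifted$z + v[3]
    expect_equal(residue_center(shifted), ctr + v)
  }
})

test_that("catalytic annotations resolve, propagate to copies, and validate", {
  s <- parse_structure(three_res_pdb())
  ann <- load_catalytic_annotation(
    data.frame(chain = "A", residue_number = c(1, 3)), s)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$index, c(1L, 3L))

  # propagation: an annotation on chain A also marks the A-2 copy
  res <- list(list(resid = "ALA", chain = "A", resno = 7,
                   atoms = list(list("CB", 0, 0, 0))),
              list(resid = "ALA", chain = "A", resno = 8,
                   atoms = list(list("CB", 5, 0, 0))))
  dimer <- parse_structure(make_pdb(res, models = 2))
  ann2 <- load_catalytic_annotation(
    data.frame(chain = "A", residue_number = 7), dimer)
  expect_setequal(ann2$chain, c("A", "A-2"))
  expect_equal(ann2$residue_number, c(7, 7))

  expect_error(load_catalytic_annotation(
    data.frame(chain = "B", residue_number = 999), s),
    "unresolvable.*B,999")
  expect_error(load_catalytic_annotation(
    data.frame(chain = character(), residue_number = integer()), s),
    "empty")
})
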