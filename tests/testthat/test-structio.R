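test_that("single fixed-column ATOM record parses element and coordinates", {
  line <- "ATOM      1  CA  ALA A   1      1.000   2.000   3.000  1.00  0.00           C"
  mol <- readProteinPDB(line)
  expect_equal(nAtoms(mol), 1L)
  expect_equal(elements(mol), "C")
  expect_equal(unname(coordMatrix(mol)[1, ]), c(1, 2, 3))
  expect_equal(structureRole(mol), "protein")
})

test_that("hydrogens and waters are filtered; all-filtered input errors", {
  lines <- c(
    pdbAtomLine(1, "H1", "ALA", "A", 1, 0, 0, 0, "H"),
    pdbAtomLine(2, "O", "HOH", "A", 2, 1, 1, 1, "O"),
    pdbAtomLine(3, "D1", "ALA", "A", 1, 2, 2, 2, "D"))
  expect_error(readProteinPDB(lines), "empty structure")
})

test_that("mixed records parse per the fixed-column layout, with element inference", {
  ## elements partly from columns 77-78, partly inferred from atom names;
  ## expected values derived by hand-slicing the fixture lines
  lines <- c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 1, 0, 0, "C"),
    pdbAtomLine(2, "N", "ALA", "A", 1, 2, 0, 0, ""),     # infer N
    pdbAtomLine(3, "O", "ALA", "A", 1, 3, 0, 0, "O"),
    pdbAtomLine(4, "SD", "MET", "A", 2, 4, 0, 0, ""),    # infer S
    pdbAtomLine(5, "CB", "MET", "A", 2, 5, 0, 0, ""))    # infer C
  mol <- readProteinPDB(lines)
  expect_equal(elements(mol), c("C", "N", "O", "S", "C"))
  expect_equal(unname(coordMatrix(mol)[, 1]), 1:5)
})

test_that("two-letter halogens are inferred from atom names by exact match", {
  lines <- c(pdbAtomLine(1, "CL1", "LIG", "A", 1, 0, 0, 0, "",
                         record = "ATOM  "),
             pdbAtomLine(2, "BR2", "LIG", "A", 1, 1, 0, 0, ""))
  mol <- readProteinPDB(lines)
  expect_equal(elements(mol), c("CL", "BR"))
})

test_that("alternate locations other than blank/'A' and HETATM handling follow the defaults", {
  lines <- c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 9, 9, 9, "C", altLoc = "B"),
    pdbAtomLine(3, "FE", "HEM", "A", 2, 1, 1, 1, "FE", record = "HETATM"))
  expect_equal(nAtoms(readProteinPDB(lines)), 1L)
  expect_equal(nAtoms(readProteinPDB(lines, includeCofactors = TRUE)), 2L)
})

test_that("unparseable coordinates raise a format error naming the line", {
  good <- pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, "C")
  bad <- sub("   0.000", "  xx.abc", good)
  expect_error(readProteinPDB(c(good, bad)), "line 2")
})

test_that("SDF parsing strips hydrogens and re-indexes bonds", {
  m <- readLigandSDF(methaneBlock())
  expect_equal(nAtoms(m), 1L)
  expect_equal(elements(m), "C")
  expect_equal(nrow(bondTable(m)), 0L)

  b <- readLigandSDF(benzeneBlock())
  expect_equal(nAtoms(b), 6L)
  expect_equal(nrow(bondTable(b)), 6L)

  ## butane with explicit H: 4 heavy atoms, 3 single bonds re-mapped to
  ## the new indexing 1-2-3-4 (manual re-indexing of the fixture)
  set.seed(1)
  bu <- readLigandSDF(butaneWithHydrogens())
  expect_equal(nAtoms(bu), 4L)
  bb <- bondTable(bu)
  expect_equal(nrow(bb), 3L)
  expect_equal(sort(paste(pmin(bb$i, bb$j), pmax(bb$i, bb$j))),
               c("1 2", "2 3", "3 4"))
  expect_true(all(bb$order == 1L))
})

test_that("counts-line mismatch is a format error", {
  lines <- methaneBlock()
  lines[4] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 99, 4)
  expect_error(readLigandSDF(lines), "counts line")
})

test_that("rotatable-bond rule: terminal, ring and chain bonds", {
  ethane <- MolecularStructure(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                               "ligand",
                               bonds = data.frame(i = 1, j = 2, order = 1L))
  expect_equal(countRotatableBonds(ethane), 0L)
  expect_equal(countRotatableBonds(readLigandSDF(benzeneBlock())), 0L)
  set.seed(1)
  expect_equal(countRotatableBonds(readLigandSDF(butaneWithHydrogens())), 1L)
})

test_that("ring detection agrees with brute-force cycle checks on random small graphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    ## random connected-ish graph: a path plus extra random edges
    edges <- data.frame(i = 1:(n - 1), j = 2:n, order = 1L)
    nExtra <- sample(0:3, 1)
    for (k in seq_len(nExtra)) {
      ij <- sort(sample.int(n, 2))
      if (any(edges$i == ij[1] & edges$j == ij[2])) next
      edges <- rbind(edges, data.frame(i = ij[1], j = ij[2], order = 1L))
    }
    coords <- matrix(stats::rnorm(3 * n), ncol = 3)
    mol <- MolecularStructure(rep("C", n), coords, "ligand", bonds = edges)
    expect_equal(countRotatableBonds(mol), bfRotatableBonds(mol))
  }
})

test_that("canonical CSV dump round-trips structures exactly", {
  set.seed(7)
  cx <- randomTestComplex(nProt = 15, nLig = 6)
  for (mol in cx) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeStructureCSV(mol, path)
    back <- readStructureCSV(path)
    expect_equal(elements(back), elements(mol))
    expect_equal(coordMatrix(back), coordMatrix(mol), tolerance = 1e-6)
    expect_equal(bondTable(back), bondTable(mol))
    expect_equal(structureRole(back), structureRole(mol))
  }
})

test_that("parsed structures never contain hydrogen", {
  expect_error(MolecularStructure("H", rbind(c(0, 0, 0)), "ligand"),
               "hydrogen")
  set.seed(3)
  bu <- readLigandSDF(butaneWithHydrogens())
  expect_false(any(elements(bu) %in% c("H", "D")))
})

test_that("PDB parsing agrees with bio3d on a multi-residue fixture", {
  skip_if_not_installed("bio3d")
  lines <- c(
    pdbAtomLine(1, "N", "GLY", "A", 1, 0.1, 0.2, 0.3, "N"),
    pdbAtomLine(2, "CA", "GLY", "A", 1, 1.1, 1.2, 1.3, "C"),
    pdbAtomLine(3, "C", "GLY", "A", 1, 2.1, 2.2, 2.3, "C"),
    pdbAtomLine(4, "O", "GLY", "A", 1, 3.1, 3.2, 3.3, "O"),
    pdbAtomLine(5, "SD", "MET", "A", 2, 4.1, 4.2, 4.3, "S"),
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  ours <- readProteinPDB(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nAtoms(ours), nrow(ref$atom))
  expect_equal(unname(coordMatrix(ours)[, 1]), ref$atom$x)
  expect_equal(elements(ours), toupper(ref$atom$elesy))
})
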