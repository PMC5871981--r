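mkStruct <- function(elems, coords, role = "protein", bonds = NULL) {
  if (is.null(bonds))
    MolecularStructure(elems, coords, role)
  else
    MolecularStructure(elems, coords, role, bonds = bonds)
}

test_that("pair counts: no eligible pairs and the single-pair case", {
  prot <- mkStruct("C", rbind(c(5, 0, 0)))
  boron <- mkStruct(c("B", "B"), rbind(c(0, 0, 0), c(1, 0, 0)), "ligand")
  expect_true(all(pairCounts(prot, boron) == 0))

  lig <- mkStruct("C", rbind(c(0, 0, 0)), "ligand")
  v <- pairCounts(prot, lig, cutoff = 12)
  expect_equal(unname(v[["C.C"]]), 1)
  expect_equal(sum(v), 1)
  expect_equal(length(v), 36L)
  expect_error(pairCounts(prot, lig, cutoff = -1), "positive")
})

test_that("pair counts equal the brute-force double loop on random complexes", {
  set.seed(11)
  for (rep in 1:10) {
    cx <- randomTestComplex(nProt = 50, nLig = 12)
    expect_equal(pairCounts(cx$protein, cx$ligand, 12),
                 structure(bfPairCounts(cx$protein, cx$ligand, 12),
                           scheme = "rf_v1"))
  }
})

test_that("Vina-style terms at characteristic surface distances", {
  ## C-C pair at surface distance 0 (r = 3.8): gauss1 = 1, repulsion = 0
  prot <- mkStruct("C", rbind(c(3.8, 0, 0)))
  lig <- mkStruct("C", rbind(c(0, 0, 0)), "ligand",
                  bonds = data.frame(i = integer(0), j = integer(0),
                                     order = integer(0)))
  v <- vinaTerms(prot, lig)
  expect_equal(unname(v[["gauss1"]]), 1)
  expect_equal(unname(v[["repulsion"]]), 0)

  ## surface distance 3 (r = 6.8): gauss2 at its mode
  prot2 <- mkStruct("C", rbind(c(6.8, 0, 0)))
  v2 <- vinaTerms(prot2, lig)
  expect_equal(unname(v2[["gauss2"]]), 1)
})

test_that("Vina-style and X-Score-like terms match per-pair hand evaluation", {
  set.seed(5)
  for (rep in 1:10) {
    cx <- randomTestComplex(nProt = 12, nLig = 8)
    expect_equal(unclass(vinaTerms(cx$protein, cx$ligand)),
                 bfVinaTerms(cx$protein, cx$ligand),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unclass(xscoreLikeTerms(cx$protein, cx$ligand)),
                 bfXscoreTerms(cx$protein, cx$ligand),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("X-Score-like terms: empty contact shell and the vdW minimum", {
  lig <- mkStruct("C", rbind(c(0, 0, 0)), "ligand",
                  bonds = data.frame(i = integer(0), j = integer(0),
                                     order = integer(0)))
  far <- mkStruct("C", rbind(c(20, 0, 0)))
  v <- xscoreLikeTerms(far, lig)
  expect_equal(as.numeric(v), c(0, 0, 0, 0))

  ## single pair at exactly r = d0: (d0/r)^8 - 2 (d0/r)^4 = -1
  touch <- mkStruct("C", rbind(c(3.8, 0, 0)))
  expect_equal(unname(xscoreLikeTerms(touch, lig)[["vdw"]]), -1)
})

test_that("42-feature scheme is the concatenation of counts and Vina terms", {
  set.seed(9)
  cx <- randomTestComplex(nProt = 30, nLig = 9)
  v3 <- rfV3Descriptors(cx$protein, cx$ligand)
  expect_length(v3, 42L)
  expect_equal(v3[1:36], pairCounts(cx$protein, cx$ligand),
               ignore_attr = TRUE)
  expect_equal(v3[37:42], vinaTerms(cx$protein, cx$ligand),
               ignore_attr = TRUE)
  expect_equal(attr(v3, "scheme"), "rf_v3")
})

test_that("unknown elements fall back to the generic radius with a warning", {
  lig <- mkStruct("XX", rbind(c(0, 0, 0)), "ligand",
                  bonds = data.frame(i = integer(0), j = integer(0),
                                     order = integer(0)))
  prot <- mkStruct("C", rbind(c(3.7, 0, 0)))
  expect_warning(v <- vinaTerms(prot, lig), "generic vdW radius")
  ## surface distance = 3.7 - 1.8 - 1.9 = 0 -> gauss1 = 1
  expect_equal(unname(v[["gauss1"]]), 1)
})

test_that("descriptors are invariant to rigid motion and atom permutation", {
  set.seed(21)
  for (rep in 1:5) {
    cx <- randomTestComplex(nProt = 25, nLig = 8)
    R <- randomRotation(); tr <- stats::rnorm(3, sd = 10)
    protR <- applyRigidMotion(cx$protein, R, tr)
    ligR <- applyRigidMotion(cx$ligand, R, tr)
    expect_equal(pairCounts(protR, ligR), pairCounts(cx$protein, cx$ligand))
    expect_equal(vinaTerms(protR, ligR), vinaTerms(cx$protein, cx$ligand),
                 tolerance = 1e-9)
    expect_equal(xscoreLikeTerms(protR, ligR),
                 xscoreLikeTerms(cx$protein, cx$ligand), tolerance = 1e-9)

    protP <- permuteAtoms(cx$protein); ligP <- permuteAtoms(cx$ligand)
    expect_equal(rfV3Descriptors(protP, ligP),
                 rfV3Descriptors(cx$protein, cx$ligand), tolerance = 1e-9)
    expect_equal(xscoreLikeTerms(protP, ligP),
                 xscoreLikeTerms(cx$protein, cx$ligand), tolerance = 1e-9)
  }
})

test_that("pair counts are monotone in the cutoff and conserve the pair total", {
  set.seed(33)
  for (rep in 1:5) {
    cx <- randomTestComplex(nProt = 30, nLig = 8)
    c6 <- pairCounts(cx$protein, cx$ligand, 6)
    c9 <- pairCounts(cx$protein, cx$ligand, 9)
    c12 <- pairCounts(cx$protein, cx$ligand, 12)
    expect_true(all(c9 >= c6) && all(c12 >= c9))
    ## conservation: total = number of eligible cross pairs within cutoff
    d <- as.vector(t(outer(rowSums(coordMatrix(cx$ligand)^2),
                           rowSums(coordMatrix(cx$protein)^2), "+") -
                     2 * tcrossprod(coordMatrix(cx$ligand),
                                    coordMatrix(cx$protein))))
    eligible <- outer(elements(cx$ligand) %in% LIG_ELEMS,
                      elements(cx$protein) %in% PROT_ELEMS, "&")
    expect_equal(sum(c12),
                 sum(sqrt(pmax(d, 0)) <= 12 & as.vector(t(eligible))))
  }
})

test_that("descriptor tables load, reject bad input, and round-trip", {
  csv <- c("id,vdw,hbond,hydrophobic,rotor,affinity",
           "c1,-3.2,2,14,5,6.4",
           "c2,-1.75,0,3,2,4.2",
           "c3,0.5,1,0,0,2.05")
  tab <- loadDescriptorTable(csv, scheme = "xscore4")
  expect_equal(complexIds(tab), c("c1", "c2", "c3"))
  expect_equal(descriptorScheme(tab), "xscore4")
  expect_equal(unname(featureMatrix(tab)[2, ]), c(-1.75, 0, 3, 2))
  expect_equal(affinities(tab), c(6.4, 4.2, 2.05))

  expect_error(loadDescriptorTable(c(csv, "c1,0,0,0,0,1"), "xscore4"),
               "duplicate id: c1")
  bad <- csv; bad[3] <- "c2,abc,0,3,2,4.2"
  expect_error(loadDescriptorTable(bad, "xscore4"), "row 2.*vdw")

  path <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorTable(tab, path)
  back <- loadDescriptorTable(path, scheme = "xscore4")
  expect_equal(featureMatrix(back), featureMatrix(tab), tolerance = 1e-5)
  expect_equal(complexIds(back), complexIds(tab))
})
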