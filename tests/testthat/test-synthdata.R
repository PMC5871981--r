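smallConfig <- function(nTrain = 120, nf = 8, nto = 4, reps = 3, ...) {
  benchmarkConfig(nTrain = nTrain,
                  familyModel = familyModel(nTestFamilies = nf,
                                            nTrainOnlyFamilies = nto,
                                            testRepresentatives = reps),
                  ...)
}

test_that("family model validity enforces separated similarity ranges", {
  expect_error(familyModel(withinRange = c(0.4, 0.9),
                           betweenRange = c(0.1, 0.5)),
               "exceed")
  expect_error(familyModel(withinRange = c(0.9, 0.8)), "ascending")
  fm <- familyModel()
  expect_equal(fm@nTestFamilies, 65L)
  expect_equal(fm@testRepresentatives, 3L)
})

test_that("single-atom ligands and contact guarantees hold by construction", {
  fam <- SFBench:::.familyParams("F1", familyModel(), 11L)
  cx <- sampleComplexGeometry(fam, nProteinAtoms = 30, nLigandAtoms = 1,
                              seed = 5)
  expect_equal(nAtoms(cx$ligand), 1L)
  expect_equal(nrow(bondTable(cx$ligand)), 0L)
  expect_equal(countRotatableBonds(cx$ligand), 0L)

  for (s in 1:5) {
    cx <- sampleComplexGeometry(fam, 40, 12, seed = s)
    expect_gt(sum(pairCounts(cx$protein, cx$ligand)), 0)
    ## chain geometry: consecutive ligand atoms 1.5 Angstrom apart
    lc <- coordMatrix(cx$ligand)
    steps <- sqrt(rowSums((lc[-1, , drop = FALSE] -
                             lc[-nrow(lc), , drop = FALSE])^2))
    expect_equal(steps, rep(1.5, nrow(lc) - 1), tolerance = 2e-3)
  }
})

test_that("geometry is bit-identical under the same seed", {
  fam <- SFBench:::.familyParams("F1", familyModel(), 3L)
  a <- sampleComplexGeometry(fam, 25, 10, seed = 77)
  b <- sampleComplexGeometry(fam, 25, 10, seed = 77)
  expect_identical(coordMatrix(a$protein), coordMatrix(b$protein))
  expect_identical(coordMatrix(a$ligand), coordMatrix(b$ligand))
  expect_identical(elements(a$ligand), elements(b$ligand))
})

test_that("similarity matrix respects family structure and range bounds", {
  set.seed(20)
  fm <- familyModel(nTestFamilies = 5, nTrainOnlyFamilies = 3)
  trainFam <- setNames(c("F001", "F002", "F006", "F007", "F008"),
                       sprintf("tr%d", 1:5))
  testFam <- setNames(rep(sprintf("F%03d", 1:5), each = 2),
                      sprintf("te%d", 1:10))
  S <- makeSimilarityMatrix(trainFam, testFam, fm, seed = 9)
  ## overlap rows peak in the within range, train-only rows stay between
  expect_gte(maxTestSimilarity(S, "tr1"), 0.75)
  expect_gte(maxTestSimilarity(S, "tr2"), 0.75)
  for (id in c("tr3", "tr4", "tr5"))
    expect_lte(maxTestSimilarity(S, id), 0.45)
  ## same-family entries only in matching columns
  v <- similarityValues(S)
  expect_true(all(v["tr1", testFam != "F001"] <= 0.45))
})

test_that("a cutoff between the ranges separates train-only families exactly", {
  cfg <- smallConfig()
  b <- makeBenchmark(cfg, 31L)
  part <- buildNestedSets(benchmarkSimilarity(b), c(0.5, 1.0))
  fams <- benchmarkFamilies(b)
  testFams <- unique(fams[benchmarkTestIds(b)])
  noOverlap <- benchmarkTrainIds(b)[!fams[benchmarkTrainIds(b)] %in%
                                      testFams]
  expect_setequal(retainedIds(part, 0.5), noOverlap)
})

test_that("benchmark split sizes and family coverage follow the configuration", {
  cfg <- smallConfig(nTrain = 90, nf = 6, nto = 3, reps = 3)
  b <- makeBenchmark(cfg, 17L)
  expect_length(benchmarkTrainIds(b), 90L)
  expect_length(benchmarkTestIds(b), 18L)
  expect_length(intersect(benchmarkTrainIds(b), benchmarkTestIds(b)), 0L)
  fams <- benchmarkFamilies(b)[benchmarkTestIds(b)]
  expect_true(all(table(fams) == 3L))
  expect_error(
    makeBenchmark(benchmarkConfig(nTrain = 0, familyModel = familyModel(
      nTestFamilies = 2, nTrainOnlyFamilies = 0))),
    ".")
})

test_that("benchmarks are a pure function of (config, master seed)", {
  cfg <- smallConfig(nTrain = 60, nf = 5, nto = 2)
  b1 <- makeBenchmark(cfg, 23L)
  b2 <- makeBenchmark(cfg, 23L)
  b3 <- makeBenchmark(cfg, 24L)
  expect_identical(benchmarkAffinities(b1), benchmarkAffinities(b2))
  expect_identical(similarityValues(benchmarkSimilarity(b1)),
                   similarityValues(benchmarkSimilarity(b2)))
  id <- benchmarkTrainIds(b1)[1]
  expect_identical(coordMatrix(benchmarkComplexes(b1)[[id]]@ligand),
                   coordMatrix(benchmarkComplexes(b2)[[id]]@ligand))
  expect_false(identical(benchmarkAffinities(b1), benchmarkAffinities(b3)))
})

test_that("noise-free linear affinities are exactly recoverable by MLR", {
  fm <- familyModel(nTestFamilies = 6, nTrainOnlyFamilies = 2, offsetSd = 0)
  cfg <- benchmarkConfig(nTrain = 120, familyModel = fm, mode = "linear",
                         noiseSd = 0)
  b <- makeBenchmark(cfg, 13L)
  tab <- benchmarkDescriptors(b, "rf_v3")
  tr <- subsetComplexes(tab, benchmarkTrainIds(b))
  te <- subsetComplexes(tab, benchmarkTestIds(b))
  m <- fitMLR(tr)
  expect_gt(pearsonRp(affinities(te), predictAffinity(m, te)), 0.99)
  expect_equal(predictAffinity(m, te), unname(affinities(te)),
               tolerance = 1e-6)
})

test_that("the linear rule recovers its own coefficients from standardized features", {
  ## generate z directly, push it through the linear rule with zero noise,
  ## and check fit_mlr returns (b, w) within 1e-6
  set.seed(30)
  p <- 5
  w <- defaultAffinityWeights(p)
  Z <- matrix(stats::rnorm(40 * p), 40, p)
  colnames(Z) <- paste0("z", 1:p)
  y <- vapply(seq_len(40), function(i)
    affinityFromDescriptors(Z[i, ], mode = "linear", weights = w),
    numeric(1))
  m <- fitMLR(DescriptorTable(sprintf("c%02d", 1:40), Z, "external", y))
  expect_equal(unname(m@fit), c(6, w), tolerance = 1e-6)
})

test_that("the nonlinear rule favours the forest over the linear fit", {
  cfg <- smallConfig(nTrain = 250, nf = 12, nto = 6)
  b <- makeBenchmark(cfg, 3L)
  tab <- benchmarkDescriptors(b, "rf_v3")
  tr <- subsetComplexes(tab, benchmarkTrainIds(b))
  te <- subsetComplexes(tab, benchmarkTestIds(b))
  rpMLR <- pearsonRp(affinities(te), predictAffinity(fitMLR(tr), te))
  rpRF <- pearsonRp(affinities(te), predictAffinity(
    fitRF(tr, spec = modelSpec("RF", nTrees = 300), seed = 1), te))
  expect_gt(rpRF, rpMLR + 0.05)
})

test_that("training on same-family complexes beats dissimilar ones across seeds", {
  ## the mechanism behind the similarity analysis: family structure in the
  ## descriptors and affinity offsets makes similar training data more
  ## valuable than an equal amount of dissimilar data
  advantages <- vapply(1:5, function(seed) {
    fm <- familyModel(nTestFamilies = 15, nTrainOnlyFamilies = 10,
                      testRepresentatives = 5)
    b <- makeBenchmark(benchmarkConfig(nTrain = 360, familyModel = fm), seed)
    tab <- benchmarkDescriptors(b, "rf_v3")
    fams <- benchmarkFamilies(b)
    teIds <- benchmarkTestIds(b)
    trIds <- benchmarkTrainIds(b)
    testFams <- unique(fams[teIds])
    same <- trIds[fams[trIds] %in% testFams]
    diffpool <- trIds[!fams[trIds] %in% testFams]
    n <- min(length(same), length(diffpool))
    same <- withSeed(seed * 11, sample(same, n))
    rnd <- withSeed(seed * 13, sample(diffpool, n))
    te <- subsetComplexes(tab, teIds)
    spec <- modelSpec("RF", nTrees = 300)
    r1 <- pearsonRp(affinities(te), predictAffinity(
      fitRF(subsetComplexes(tab, same), spec = spec, seed = 1), te))
    r2 <- pearsonRp(affinities(te), predictAffinity(
      fitRF(subsetComplexes(tab, rnd), spec = spec, seed = 1), te))
    r1 - r2
  }, numeric(1))
  expect_gt(mean(advantages), 0)
  expect_gte(sum(advantages > 0), 3L)
})

test_that("exported benchmarks re-import identically", {
  cfg <- smallConfig(nTrain = 40, nf = 4, nto = 2)
  b <- makeBenchmark(cfg, 19L)
  dir <- withr::local_tempdir()
  exportBenchmark(b, dir)
  back <- importBenchmark(dir)
  expect_setequal(names(back$complexes), names(benchmarkComplexes(b)))
  expect_equal(back$trainIds, benchmarkTrainIds(b))
  expect_equal(back$testIds, benchmarkTestIds(b))
  expect_equal(similarityValues(back$similarity),
               similarityValues(benchmarkSimilarity(b)))
  for (id in names(back$complexes)[c(1, 10, 25)]) {
    orig <- benchmarkComplexes(b)[[id]]
    expect_equal(coordMatrix(back$complexes[[id]]$protein),
                 coordMatrix(orig@protein))
    expect_equal(coordMatrix(back$complexes[[id]]$ligand),
                 coordMatrix(orig@ligand))
    expect_equal(elements(back$complexes[[id]]$ligand),
                 elements(orig@ligand))
    expect_equal(bondTable(back$complexes[[id]]$ligand),
                 bondTable(orig@ligand))
    expect_equal(back$complexes[[id]]$affinity, unname(orig@affinity))
  }
})
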