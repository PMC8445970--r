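test_that("the same spec and seed reproduce the dataset byte for byte", {
  spec <- syntheticSpec(nMolecules = 50, nFeatures = 40, nConstant = 8,
                        nInformative = 3, nRedundant = 5, labelNoise = 0.1,
                        seed = 77)
  g1 <- generateDataset(spec)
  g2 <- generateDataset(spec)
  expect_identical(descriptorMatrix(g1$dataset), descriptorMatrix(g2$dataset))
  expect_identical(as.character(classLabels(g1$dataset)),
                   as.character(classLabels(g2$dataset)))
  expect_identical(g1$truth, g2$truth)
  # a different seed changes the draw
  g3 <- generateDataset(syntheticSpec(nMolecules = 50, nFeatures = 40,
                                      nConstant = 8, nInformative = 3,
                                      nRedundant = 5, labelNoise = 0.1,
                                      seed = 78))
  expect_false(identical(descriptorMatrix(g1$dataset),
                         descriptorMatrix(g3$dataset)))
})

test_that("class counts are exact for the emulated screen sizes", {
  tox <- generateDataset(syntheticSpec(nMolecules = 171, nFeatures = 60,
                                       nConstant = 10, nInformative = 4,
                                       nRedundant = 4,
                                       positiveFraction = 0.33, seed = 1))
  expect_identical(unname(classCounts(tox$dataset)), c(171L, 56L, 115L))

  per <- generateDataset(syntheticSpec(nMolecules = 90, nFeatures = 60,
                                       nConstant = 10, nInformative = 4,
                                       nRedundant = 4,
                                       positiveFraction = 0.30,
                                       positiveClass = "lengthener",
                                       negativeClass = "nochange", seed = 2))
  expect_identical(unname(classCounts(per$dataset)), c(90L, 27L, 63L))

  # label noise must not disturb the printed counts (paired swaps)
  noisy <- generateDataset(syntheticSpec(nMolecules = 171, nFeatures = 60,
                                         nConstant = 10, nInformative = 4,
                                         nRedundant = 4, labelNoise = 0.1,
                                         seed = 3))
  expect_identical(unname(classCounts(noisy$dataset)), c(171L, 56L, 115L))
  flipped <- sum(as.character(classLabels(noisy$dataset)) !=
                   unname(noisy$truth$labelsPreflip))
  expect_identical(flipped, 2L * as.integer(round(0.1 * 171 / 2)))
})

test_that("planted structure matches the recorded ground truth", {
  spec <- syntheticSpec(nMolecules = 80, nFeatures = 50, nConstant = 12,
                        nInformative = 4, nRedundant = 6,
                        blockCorrelation = 0.9, labelNoise = 0, seed = 5)
  gen <- generateDataset(spec)
  m <- descriptorMatrix(gen$dataset)

  # constant features literally constant, and exactly the declared count
  expect_length(gen$truth$constant, 12L)
  for (f in gen$truth$constant)
    expect_identical(length(unique(m[, f])), 1L)
  cleaned <- dropConstantFeatures(gen$dataset)
  expect_setequal(cleaningReport(cleaned)$removedConstant, gen$truth$constant)

  # redundant copies correlate with their mapped informative source
  for (r in names(gen$truth$redundantMap)) {
    src <- gen$truth$redundantMap[[r]]
    expect_true(src %in% gen$truth$informative)
    expect_gt(cor(m[, r], m[, src]), 0.8)
  }

  # categories are disjoint
  expect_length(intersect(gen$truth$informative, gen$truth$constant), 0L)
  expect_length(intersect(gen$truth$informative,
                          names(gen$truth$redundantMap)), 0L)
})

test_that("axis_threshold with one informative feature is stump-separable", {
  spec <- syntheticSpec(nMolecules = 60, nFeatures = 10, nConstant = 0,
                        nInformative = 1, nRedundant = 0,
                        boundary = "axis_threshold", labelNoise = 0, seed = 8)
  gen <- generateDataset(spec)
  ds <- gen$dataset
  est <- estimatorSpec("decision_tree", params = list(max_depth = 1), seed = 1)
  model <- qsarselect:::.fitModel(est, descriptorMatrix(ds), classLabels(ds),
                                  sampleWeights(ds))
  pred <- qsarselect:::.predictModel(model, descriptorMatrix(ds))
  expect_identical(pred, classLabels(ds))   # 100% training accuracy at depth 1
})

test_that("recovery score follows its definition", {
  truth <- list(informative = c("A", "B"),
                redundantMap = c(R1 = "A"),
                constant = character(0))
  expect_identical(recoveryScore(c("A", "B"), truth), 1)
  expect_identical(recoveryScore(c("x", "y"), truth), 0)
  expect_identical(recoveryScore(c("A", "R1", "x", "y"), truth), 0.5)
  expect_identical(recoveryScore(character(0), truth), 0)
})

test_that("infeasible specs are rejected", {
  expect_error(syntheticSpec(nFeatures = 20, nConstant = 10,
                             nInformative = 8, nRedundant = 8), "infeasible")
  expect_error(syntheticSpec(labelNoise = 0.6), "labelNoise")
  expect_error(syntheticSpec(positiveFraction = 0), "positiveFraction")
  expect_error(syntheticSpec(boundary = "xor_pair", nInformative = 1),
               "xor_pair")
})
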