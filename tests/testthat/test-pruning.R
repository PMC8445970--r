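# shared toy: 2 informative + 3 noise features, mild label noise so
# accuracies are informative but not saturated
makePruningDataset <- function(seed = 1L) {
  spec <- syntheticSpec(nMolecules = 60, nFeatures = 5, nConstant = 0,
                        nInformative = 2, nRedundant = 0,
                        boundary = "additive_threshold", labelNoise = 0.05,
                        seed = seed)
  generateDataset(spec)
}

test_that("each pruning step matches an exhaustive single-deletion oracle", {
  gen <- makePruningDataset(3)
  ds <- gen$dataset
  est <- estimatorSpec("decision_tree", params = list(max_depth = 4), seed = 2)
  cv <- cvConfig(reps = 3, baseSeed = 41)
  trace <- backwardPrune(ds, descriptorNames(ds), est, cv, extraSteps = 10L)

  # independent exhaustive loop, same paired seeds, argmax by
  # (mean desc, std asc, name asc)
  current <- descriptorNames(ds)
  for (i in seq_len(nrow(trace$steps) - 1L)) {
    cand <- t(vapply(current, function(f) {
      r <- repeatedCV(ds, setdiff(current, f), est, cv)
      c(mean = r$mean, std = r$std)
    }, numeric(2)))
    ord <- order(-cand[, "mean"], cand[, "std"], rownames(cand))
    expected <- rownames(cand)[ord[1L]]
    expect_identical(trace$steps$Removed[i + 1L], expected)
    # per-step optimality: the pruned candidate's mean tops every other
    expect_true(all(cand[expected, "mean"] >= cand[, "mean"]))
    current <- setdiff(current, expected)
  }
  expect_length(trace$bestSet,
                trace$steps$Features[which.max(trace$steps$Mean)])
  expect_true(all(trace$bestSet %in% descriptorNames(ds)))
})

test_that("an exact duplicate column is pruned first at unchanged accuracy", {
  ds0 <- makeSeparableDataset(n = 60, nNoise = 2, seed = 12)
  m <- descriptorMatrix(ds0)
  m <- cbind(m, a_dup = m[, "f_sep"])   # lexicographically first duplicate
  ds <- joinLabels(DescriptorSet(m),
                   setNames(as.character(classLabels(ds0)), rownames(m)),
                   "pos")
  est <- estimatorSpec("decision_tree", params = list(max_depth = 1), seed = 1)
  cv <- cvConfig(reps = 3, baseSeed = 9)
  trace <- backwardPrune(ds, colnames(m), est, cv, extraSteps = 1L)
  expect_true(trace$steps$Removed[2L] %in% c("a_dup", "f_sep"))
  # paired seeds: deleting a duplicate leaves accuracy exactly unchanged
  expect_identical(trace$steps$Mean[2L], trace$steps$Mean[1L])
})

test_that("a 2-feature start set yields a single evaluation step", {
  gen <- makePruningDataset(5)
  feats <- utils::head(descriptorNames(gen$dataset), 2L)
  trace <- backwardPrune(gen$dataset, feats,
                         estimatorSpec("decision_tree", seed = 1),
                         cvConfig(reps = 2, baseSeed = 1))
  expect_identical(nrow(trace$steps), 1L)
  expect_identical(trace$bestSet, feats)
  expect_error(backwardPrune(gen$dataset, feats[1],
                             estimatorSpec("decision_tree", seed = 1)),
               "at least 2")
})

test_that("trace bookkeeping: cardinality falls by one, best set is the argmax", {
  gen <- makePruningDataset(7)
  trace <- backwardPrune(gen$dataset, descriptorNames(gen$dataset),
                         estimatorSpec("decision_tree",
                                       params = list(max_depth = 4), seed = 3),
                         cvConfig(reps = 3, baseSeed = 2), extraSteps = 10L)
  expect_identical(diff(trace$steps$Features), rep(-1L, nrow(trace$steps) - 1L))
  expect_true(is.na(trace$steps$Removed[1L]))
  expect_identical(trace$bestCardinality,
                   trace$steps$Features[which.max(trace$steps$Mean)])
  expect_length(trace$bestSet, trace$bestCardinality)
  expect_true(all(trace$bestSet %in% descriptorNames(gen$dataset)))
})

test_that("per-step retuning sweeps the named parameter", {
  gen <- makePruningDataset(11)
  trace <- backwardPrune(gen$dataset, descriptorNames(gen$dataset),
                         estimatorSpec("decision_tree",
                                       params = list(max_depth = NA), seed = 1),
                         cvConfig(reps = 2, baseSeed = 5),
                         extraSteps = 1L, retune = "max_depth",
                         retuneGrid = list(max_depth = c(2L, 6L)))
  expect_true(trace$estimator$params$max_depth %in% c(2L, 6L))
})

test_that("pruning removes noise before planted signal in most seeded runs", {
  ok <- 0L
  for (seed in 1:20) {
    spec <- syntheticSpec(nMolecules = 60, nFeatures = 5, nConstant = 0,
                          nInformative = 2, nRedundant = 0,
                          boundary = "additive_threshold", labelNoise = 0.05,
                          seed = 100 + seed)
    gen <- generateDataset(spec)
    trace <- backwardPrune(gen$dataset, descriptorNames(gen$dataset),
                           estimatorSpec("decision_tree",
                                         params = list(max_depth = 3),
                                         seed = seed),
                           cvConfig(reps = 5, baseSeed = seed),
                           extraSteps = 10L)
    removed <- trace$steps$Removed[-1L]
    firstInf <- which(removed %in% gen$truth$informative)[1L]
    nNoiseBefore <- if (is.na(firstInf)) sum(!removed %in% gen$truth$informative)
                    else firstInf - 1L
    # success: every pure-noise feature is pruned before any informative one
    if (nNoiseBefore >= 3L) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.8)
})
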