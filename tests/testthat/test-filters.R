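# range-gate training, reduction, intersection and application

test_that("training subsets are deterministic, capped and validated", {
  ds <- smallDataset(60, seed = 1)
  ids <- sampleTraining(ds, "Cryptomonas", 25, seed = 4)
  expect_length(ids, 25L)
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(trueLabels(ds)[ids] == "Cryptomonas"))
  expect_identical(ids, sampleTraining(ds, "Cryptomonas", 25, seed = 4))
  expect_false(identical(ids, sampleTraining(ds, "Cryptomonas", 25, seed = 5)))
  expect_error(sampleTraining(ds, "Cryptomonas", 61, seed = 1),
               "insufficient")
  # pool cap: only the first 150 class members are eligible
  big <- smallDataset(160, seed = 2)
  ids2 <- sampleTraining(big, "Micractinium", 50, seed = 1, poolCap = 150L)
  pool <- which(trueLabels(big) == "Micractinium")[1:150]
  expect_true(all(ids2 %in% pool))
})

test_that("fitRanges takes the subset min/max envelope", {
  ds <- smallDataset(30, seed = 3)
  ids <- which(trueLabels(ds) == "Cryptomonas")[1:3]
  f <- fitRanges(ds, ids, "Cryptomonas", c("diameterABD", "intensity"))
  sub <- featureTable(ds)[ids, ]
  expect_equal(gates(f)$min, c(min(sub$diameterABD), min(sub$intensity)))
  expect_equal(gates(f)$max, c(max(sub$diameterABD), max(sub$intensity)))

  # degenerate single-image subset
  f1 <- fitRanges(ds, ids[1], "Cryptomonas", "intensity")
  expect_equal(gates(f1)$min, gates(f1)$max)

  # adding an interior point leaves the envelope unchanged
  mid <- which.min(abs(featureTable(ds)$intensity[ids] -
                       mean(range(featureTable(ds)$intensity[ids]))))
  f2 <- fitRanges(ds, ids, "Cryptomonas", "intensity")
  f3 <- fitRanges(ds, c(ids, ids[mid]), "Cryptomonas", "intensity")
  expect_equal(gates(f2), gates(f3))

  expect_error(fitRanges(ds, ids, "Cryptomonas", "volume"), "unknown feature")
})

test_that("greedy reduction finds the single separating gate", {
  ds <- separableDataset()
  ids <- which(trueLabels(ds) == "A")
  full <- fitRanges(ds, ids, "A")
  red <- reduceFeatures(full, ds, 0.75)
  expect_equal(nrow(gates(red)), 1L)
  expect_equal(gates(red)$feature, "intensity")
  expect_gt(colonyGate:::.filterAccuracy(red, featureTable(ds),
                                         trueLabels(ds)), 0.75)
})

test_that("greedy reduction matches exhaustive search on small gate sets", {
  # exhaustive oracle over every subset of <= 8 starting gates
  ds <- separableDataset(30, seed = 9)
  feats8 <- cgFeatureNames()[1:8]
  ids <- which(trueLabels(ds) == "A")
  full <- fitRanges(ds, ids, "A", feats8)
  red <- reduceFeatures(full, ds, 0.75)
  ft <- featureTable(ds); lb <- trueLabels(ds)
  accOf <- function(keep) {
    f <- full; f@gates <- full@gates[keep, , drop = FALSE]
    colonyGate:::.filterAccuracy(f, ft, lb)
  }
  sizes <- integer(0); accs <- numeric(0)
  for (k in 1:8) {
    cmb <- utils::combn(8, k)
    best <- max(apply(cmb, 2, accOf))
    sizes <- c(sizes, k); accs <- c(accs, best)
  }
  minimalSize <- min(sizes[accs > 0.75])
  expect_equal(nrow(gates(red)), minimalSize)
  expect_gt(colonyGate:::.filterAccuracy(red, ft, lb), 0.75)
  # minimality: dropping any remaining gate would breach the floor
  if (nrow(gates(red)) > 1L) {
    for (i in seq_len(nrow(gates(red)))) {
      f <- red; f@gates <- gates(red)[-i, , drop = FALSE]
      expect_lte(colonyGate:::.filterAccuracy(f, ft, lb), 0.75)
    }
  }
})

test_that("reduction warns and returns the input when already at the floor", {
  ds <- separableDataset()
  # a filter whose gates select everything: accuracy = share of negatives
  allPass <- RangeFilter("A", data.frame(feature = "intensity",
                                         min = -Inf, max = Inf))
  expect_warning(out <- reduceFeatures(allPass, ds, 0.75), "unchanged")
  expect_equal(gates(out), gates(allPass))
})

test_that("intersection narrows to the published worked-example ranges", {
  nova25 <- RangeFilter("Microcystis novacekii",
                        data.frame(feature = "diameterABD",
                                   min = 45.35, max = 85.69), "25")
  nova50 <- RangeFilter("Microcystis novacekii",
                        data.frame(feature = "diameterABD",
                                   min = 33.48, max = 83.89), "50")
  g <- gates(intersectFilters(nova25, nova50))
  expect_equal(c(g$min, g$max), c(45.35, 83.89))

  ich25 <- RangeFilter("Microcystis ichthyoblabe",
                       data.frame(feature = "averageBlue",
                                  min = 72.02, max = 96.30), "25")
  ich50 <- RangeFilter("Microcystis ichthyoblabe",
                       data.frame(feature = "averageBlue",
                                  min = 77.64, max = 96.30), "50")
  g <- gates(intersectFilters(ich25, ich50))
  expect_equal(c(g$min, g$max), c(77.64, 96.30))

  # idempotence, class mismatch, empty overlap
  expect_equal(gates(intersectFilters(nova25, nova25)), gates(nova25))
  expect_error(intersectFilters(nova25, ich25), "class mismatch")
  lo <- RangeFilter("x", data.frame(feature = "intensity", min = 1, max = 2))
  hi <- RangeFilter("x", data.frame(feature = "intensity", min = 3, max = 4))
  expect_error(intersectFilters(lo, hi), "empty intersection")

  # a feature present in only one parent carries over unchanged
  two <- RangeFilter("x", data.frame(feature = c("intensity", "roughness"),
                                     min = c(1, 1), max = c(10, 2)))
  one <- RangeFilter("x", data.frame(feature = "intensity", min = 2, max = 8))
  g <- gates(intersectFilters(two, one))
  expect_equal(g[g$feature == "roughness", c("min", "max")],
               data.frame(min = 1, max = 2, row.names = 2L))
})

test_that("filter application uses inclusive conjunction semantics", {
  ds <- separableDataset()
  fA <- RangeFilter("A", data.frame(feature = "intensity", min = 10, max = 20))
  fB <- RangeFilter("B", data.frame(feature = "intensity", min = 30, max = 40))
  fs <- new("FilterSet", filters = list(A = fA, B = fB), metadata = list())
  res <- applyFilters(fs, ds)
  sel <- selections(res)
  expect_true(all(sel[trueLabels(ds) == "A", "A"]))
  expect_false(any(sel[trueLabels(ds) == "A", "B"]))

  # boundary values are selected (inclusive bounds)
  ft <- featureTable(ds)
  bnd <- ds[1]
  bnd@features$intensity <- 20
  expect_true(selections(applyFilters(fs, bnd))[1, "A"])

  # particle failing one gate of a class is not selected by that class
  fA2 <- RangeFilter("A", data.frame(feature = c("intensity", "roughness"),
                                     min = c(10, 99), max = c(20, 100)))
  fs2 <- new("FilterSet", filters = list(A = fA2), metadata = list())
  expect_false(any(selections(applyFilters(fs2, ds))))

  expect_error(applyFilters(fs, new("ParticleDataset",
    features = featureTable(ds)["diameterABD"], labels = character(0),
    meta = sampleMeta(ds)[0, ])), "missing feature")
})

test_that("narrowing any gate only shrinks the selected set", {
  ds <- smallDataset(50, seed = 12)
  set.seed(30)
  for (i in 1:20) {
    cl <- sample(unique(trueLabels(ds)), 1)
    ids <- sampleTraining(ds, cl, 25, seed = i)
    f <- fitRanges(ds, ids, cl, sample(cgFeatureNames(), 3))
    fs <- new("FilterSet", filters = stats::setNames(list(f), cl),
              metadata = list())
    base <- selections(applyFilters(fs, ds))[, 1]
    g <- gates(f)
    j <- sample(nrow(g), 1)
    width <- g$max[j] - g$min[j]
    g$min[j] <- g$min[j] + 0.25 * width
    g$max[j] <- g$max[j] - 0.25 * width
    fNarrow <- RangeFilter(cl, g)
    fsN <- new("FilterSet", filters = stats::setNames(list(fNarrow), cl),
               metadata = list())
    narrow <- selections(applyFilters(fsN, ds))[, 1]
    expect_true(all(base | !narrow))   # narrow subset of base
  }
})

test_that("exclusive mode assigns the first selecting class in priority order", {
  ds <- separableDataset()
  both <- RangeFilter("A", data.frame(feature = "intensity", min = 0, max = 50))
  fB <- RangeFilter("B", data.frame(feature = "intensity", min = 30, max = 40))
  fs <- new("FilterSet", filters = list(A = both, B = fB), metadata = list())
  res <- applyFilters(fs, ds, mode = "exclusive", priority = c("B", "A"))
  ex <- exclusiveLabels(res)
  expect_true(all(ex[trueLabels(ds) == "B"] == "B"))
  expect_true(all(ex[trueLabels(ds) == "A"] == "A"))
  # nothing selected -> unclassified
  none <- RangeFilter("A", data.frame(feature = "intensity", min = 99,
                                      max = 100))
  fs0 <- new("FilterSet", filters = list(A = none), metadata = list())
  expect_true(all(exclusiveLabels(applyFilters(fs0, ds,
                                               mode = "exclusive")) ==
                  "unclassified"))
})

test_that("intersection selections are nested within both parents", {
  ds <- smallDataset(60, seed = 21)
  cls <- unique(trueLabels(ds))
  fs25 <- trainFilterSet(ds, cls, n = 25, seed = 2, reduce = FALSE)
  fs50 <- trainFilterSet(ds, cls, n = 50, seed = 44, reduce = FALSE)
  fsI <- intersectFilterSets(fs25, fs50)
  s25 <- selections(applyFilters(fs25, ds))
  s50 <- selections(applyFilters(fs50, ds))
  sI <- selections(applyFilters(fsI, ds))
  expect_true(all(s25 | !sI))
  expect_true(all(s50 | !sI))
})

test_that("filter files round-trip bit-exactly", {
  ds <- smallDataset(60, seed = 7)
  fs <- trainFilterSet(ds, n = 25, seed = 3)
  p1 <- tempfile(fileext = ".txt")
  writeFilterSet(fs, p1)
  back <- readFilterSet(p1)
  expect_equal(names(back@filters), names(fs@filters))
  for (cl in names(fs@filters))
    expect_identical(gates(back@filters[[cl]]), gates(fs@filters[[cl]]))
  p2 <- tempfile(fileext = ".txt")
  writeFilterSet(back, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
})

test_that("trainFilterSet regenerates deterministically from its metadata", {
  ds <- smallDataset(60, seed = 10)
  a <- trainFilterSet(ds, n = 25, seed = 9)
  b <- trainFilterSet(ds, n = 25, seed = 9)
  expect_equal(lapply(a@filters, gates), lapply(b@filters, gates))
  expect_identical(trainingIds(a), trainingIds(b))
})
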