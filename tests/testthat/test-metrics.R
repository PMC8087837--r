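# validation metrics: fixed points, hand values, independent oracles

test_that("overall accuracy matches hand evaluation", {
  expect_equal(gateAccuracy(5, 5, 10), 1)
  expect_equal(gateAccuracy(0, 0, 10), 0)
  expect_equal(gateAccuracy(3, 5, 10), 0.8)
  expect_error(gateAccuracy(3, 5, 0))
  expect_error(gateAccuracy(7, 5, 10))
})

resultFrom <- function(sel, truth) {
  new("ClassificationResult", selections = sel, exclusive = character(0),
      truth = truth)
}

test_that("confusion counts, precision and FDR are complementary", {
  truth <- c(rep("a", 10), rep("b", 100))
  sel <- cbind(a = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 10),
                     rep(FALSE, 90)),
               b = c(rep(FALSE, 10), rep(TRUE, 90), rep(FALSE, 10)))
  cm <- confusionCounts(resultFrom(sel, truth))
  st <- gateStats(cm)
  expect_equal(st["a", "TP"], 8)
  expect_equal(st["a", "FP"], 10)
  expect_equal(gateCounts(cm)["a", "b"], 10)
  expect_equal(st$precision + st$fdr, c(1, 1))
  expect_equal(sum(gateCounts(cm)["a", ]), st["a", "TP"] + st["a", "FP"])

  # balanced accuracy: 8/10 positives, 90/100 negatives -> 0.85
  expect_equal(balancedAccuracy(cm, "a"), (0.8 + 0.9) / 2)

  # perfect classifier and select-everything classifier
  selP <- cbind(a = truth == "a", b = truth == "b")
  cmP <- confusionCounts(resultFrom(selP, truth))
  expect_equal(balancedAccuracy(cmP, "a"), 1)
  selAll <- cbind(a = rep(TRUE, 110), b = rep(TRUE, 110))
  expect_equal(balancedAccuracy(confusionCounts(resultFrom(selAll, truth)),
                                "a"), 0.5)

  expect_error(balancedAccuracy(cm, "zz"), "unknown")
  cmDeg <- confusionCounts(resultFrom(cbind(z = rep(TRUE, 4)),
                                      rep("z", 4)))
  expect_error(balancedAccuracy(cmDeg, "z"), "degenerate")
})

test_that("Hellinger distance fixed points and hand value", {
  expect_equal(hellingerDistance(c(2, 4, 6), c(1, 2, 3))$mean, 0)
  expect_equal(hellingerDistance(c(5, 0), c(0, 7))$mean, 1)
  # proportions (1, 0) vs (0.5, 0.5): (1/sqrt(2)) sqrt(2 - sqrt(2))
  expect_equal(hellingerDistance(c(10, 0), c(5, 5))$mean,
               sqrt(2 - sqrt(2)) / sqrt(2), tolerance = 1e-12)
  # symmetric in its two arguments
  x <- c(3, 9, 1); t <- c(4, 4, 8)
  expect_equal(hellingerDistance(x, t)$mean, hellingerDistance(t, x)$mean)
  # per-filter-set rows and the overall mean
  X <- rbind(c(10, 0), c(5, 5)); T2 <- rbind(c(5, 5), c(5, 5))
  hd <- hellingerDistance(X, T2)
  expect_length(hd$perSet, 2L)
  expect_equal(hd$mean, mean(hd$perSet))
  expect_true(all(hd$perSet >= 0 & hd$perSet <= 1))
  expect_error(hellingerDistance(c(0, 0), c(1, 2)), "zero total")
})

test_that("SMAPE per class: fixed points and bounds", {
  expect_equal(smapePerClass(c(4, 7), c(4, 7)), 0)
  expect_equal(smapePerClass(10, 30), 50)
  expect_equal(smapePerClass(10, 0), 100)
  expect_equal(smapePerClass(0, 0), 0)     # 0/0 term defined as 0
  expect_equal(smapePerClass(c(10, 0), c(10, 5)), 50)
})

test_that("Bray-Curtis dissimilarity fixed points and vegan agreement", {
  expect_equal(brayCurtis(c(7, 3), c(7, 3)), 0)
  expect_equal(brayCurtis(c(10, 0), c(0, 10)), 1)
  expect_equal(brayCurtis(c(10, 30), c(20, 20)), 0.25)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:20) {
    a <- stats::rpois(6, 20); b <- stats::rpois(6, 20)
    if (sum(a + b) == 0) next
    expect_equal(brayCurtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("KL divergence: fixed points, nonnegativity, asymmetry, guards", {
  expect_equal(klDivergence(c(3, 3, 6), c(1, 1, 2)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5), base = 2), 1,
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:200) {
    a <- stats::rpois(5, 10) + 1; b <- stats::rpois(5, 10) + 1
    expect_gte(klDivergence(a, b), -1e-12)
  }
  a <- c(6, 3, 1); b <- c(2, 5, 3)
  expect_false(isTRUE(all.equal(klDivergence(a, b), klDivergence(b, a))))
  expect_error(klDivergence(c(2, 1), c(1, 0)), "infinite divergence")
  expect_silent(klDivergence(c(2, 1), c(1, 0), pseudocount = 0.5))
})

test_that("each metric matches an independently coded brute-force oracle", {
  # oracles written as explicit element loops over the printed formulas
  hdOracle <- function(X, T2) {
    s <- nrow(X); c <- ncol(X)
    tot <- 0
    for (f in 1:s) {
      inner <- 0
      for (k in 1:c)
        inner <- inner + (sqrt(X[f, k] / sum(X)) - sqrt(T2[f, k] / sum(T2)))^2
      tot <- tot + sqrt(inner) / sqrt(2)
    }
    tot / s
  }
  smapeOracle <- function(a, f) {
    s <- length(a); acc <- 0
    for (i in 1:s) {
      den <- a[i] + f[i]
      if (den > 0) acc <- acc + abs(a[i] - f[i]) / den
    }
    100 * acc / s
  }
  bcOracle <- function(a, f) {
    num <- 0; den <- 0
    for (k in seq_along(a)) { num <- num + abs(a[k] - f[k]); den <- den + a[k] + f[k] }
    num / den
  }
  klOracle <- function(a, f) {
    p <- a / sum(a); q <- f / sum(f); acc <- 0
    for (k in seq_along(a)) if (p[k] > 0) acc <- acc + p[k] * log(p[k] / q[k])
    acc
  }
  accOracle <- function(tp, tn, total) (tn + tp) / total

  set.seed(101)
  for (i in 1:100) {
    s <- sample(1:4, 1); c <- sample(2:6, 1)
    X <- matrix(stats::rpois(s * c, 15) + 1, s, c)
    T2 <- matrix(stats::rpois(s * c, 15) + 1, s, c)
    expect_equal(hellingerDistance(X, T2)$mean, hdOracle(X, T2),
                 tolerance = 1e-12)
    a <- X[, 1]; f <- T2[, 1]
    expect_equal(smapePerClass(a, f), smapeOracle(a, f), tolerance = 1e-12)
    expect_equal(brayCurtis(X[1, ], T2[1, ]), bcOracle(X[1, ], T2[1, ]),
                 tolerance = 1e-12)
    expect_equal(klDivergence(X[1, ], T2[1, ]), klOracle(X[1, ], T2[1, ]),
                 tolerance = 1e-12)
    tp <- sample(0:20, 1); tn <- sample(0:20, 1)
    expect_equal(gateAccuracy(tp, tn, 40), accOracle(tp, tn, 40),
                 tolerance = 1e-12)
  }
})

test_that("evaluateFilterSet produces the summary-table metric columns", {
  truth <- rep(c("a", "b"), each = 50)
  selP <- cbind(a = truth == "a", b = truth == "b")
  rep0 <- evaluateFilterSet(resultFrom(selP, truth),
                            trainResult = resultFrom(selP, truth))
  expect_s4_class(rep0, "MetricReport")
  expect_named(rep0@perClass, c("class", "hellinger", "balancedAccuracy",
                                "smape", "precision", "fdr"))
  expect_equal(rep0@perClass$precision, c(1, 1))
  expect_equal(rep0@perClass$fdr, c(0, 0))
  expect_equal(rep0@perClass$balancedAccuracy, c(1, 1))
  expect_equal(rep0@perClass$smape, c(0, 0))
  expect_equal(rep0@overall$brayCurtis, 0)
  expect_equal(rep0@overall$klDivergence, 0)
  expect_equal(rep0@overall$accuracy, 1)
  expect_equal(rep0@perClass$hellinger, c(0, 0))

  # random classifier on two balanced classes: balanced accuracy ~ 0.5
  set.seed(33)
  truthR <- rep(c("a", "b"), each = 2000)
  selR <- cbind(a = stats::runif(4000) < 0.5, b = stats::runif(4000) < 0.5)
  repR <- evaluateFilterSet(resultFrom(selR, truthR))
  expect_equal(repR@perClass$balancedAccuracy, c(0.5, 0.5), tolerance = 0.05)

  # CSV mirror of the summary table
  p <- tempfile(fileext = ".csv")
  writeMetricReport(rep0, p)
  hdr <- names(utils::read.csv(p, check.names = FALSE))
  expect_equal(hdr, c("filter set", "Hellinger distance",
                      "Balanced accuracy (%)", "SMAPE (%)",
                      "Bray-Curtis dissimilarity",
                      "Kullback-Leibler Divergence"))
})
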