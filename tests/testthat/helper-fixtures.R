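# shared fixtures: tiny frames and masks built in code

# uniform background frame with a dark axis-aligned rectangle
rectFrame <- function(side = 40, rows = 10:30, cols = 10:30, level = 90,
                      bg = 230, pixelSizeUm = 1) {
  px <- matrix(bg, side, side)
  px[rows, cols] <- level
  ParticleImage(px, pixelSizeUm)
}

# frame with a centred dark disk of radius r
diskFrame <- function(side, r, level = 90, bg = 230, pixelSizeUm = 1) {
  px <- matrix(bg, side, side)
  ctr <- (side + 1) / 2
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+")
  px[d2 <= r^2] <- level
  ParticleImage(px, pixelSizeUm)
}

logicalMask <- function(m) {
  new("ParticleMask", mask = m, areaPx = sum(m),
      holeCount = colonyGate:::.countHoles(m))
}

# small three-class feature table with prescribed separability, table mode
smallDataset <- function(nPerClass = 60, seed = 1) {
  profs <- defaultProfiles()[c("Cryptomonas", "Micractinium",
                               "Microcystis novacekii")]
  generateDataset(GenerationConfig(profiles = profs, nPerClass = nPerClass,
                                   seed = seed, mode = "table"))
}

refFilterPath <- function(name) {
  system.file("extdata", "filtersets", name, package = "colonyGate",
              mustWork = TRUE)
}

# brute-force caliper oracle: project *all* pixel-corner points
feretOracle <- function(m, px = 1) {
  idx <- which(m, arr.ind = TRUE)
  x <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  y <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  best <- 0
  for (deg in seq(0, 175, by = 5)) {
    a <- deg * pi / 180
    p <- x * cos(a) + y * sin(a)
    best <- max(best, max(p) - min(p))
  }
  best * px
}

# small labeled dataset where exactly one feature separates the class
separableDataset <- function(n = 40, seed = 6) {
  set.seed(seed)
  feats <- as.data.frame(matrix(stats::runif(2 * n * 10, 40, 60), ncol = 10))
  names(feats) <- cgFeatureNames()
  feats$roughness <- pmax(feats$roughness / 40, 1)
  labels <- rep(c("A", "B"), each = n)
  feats$intensity <- c(stats::runif(n, 10, 20), stats::runif(n, 30, 40))
  meta <- data.frame(id = sprintf("p%03d", seq_len(2 * n)), tank = "A1",
                     date = "2019-06-04")
  new("ParticleDataset", features = feats, labels = labels, meta = meta)
}

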