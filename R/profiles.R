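#' Construct a MorphProfile
#'
#' @param classLabel class label.
#' @param nCells length-2 range of colony cell counts (`c(1, 1)` renders a
#'   single cell).
#' @param cellRadiusUm length-2 range, cell radius in um.
#' @param colonySpreadUm length-2 range, colony spread in um.
#' @param holeFraction expected holes per placed cell, in \[0, 1\].
#' @param haloStrength halo ramp width in pixels (0 disables the halo).
#' @param intensitySd length-2 range of grayscale texture sd; defaults to
#'   `latent$sigmaIntensity`.
#' @param latent named list of length-2 draw ranges keyed by canonical
#'   feature names; must contain at least `intensity`, `ratioRedBlue`,
#'   `ratioRedGreen`, `sigmaIntensity` and `diameterABD`.
#' @param envelope named list of length-2 feature envelopes the rendered
#'   class is expected to satisfy (used by the generator self-consistency
#'   checks).
#' @return A [MorphProfile-class].
#' @export
MorphProfile <- function(classLabel, nCells, cellRadiusUm, colonySpreadUm,
                         holeFraction = 0, haloStrength = 0,
                         intensitySd = latent$sigmaIntensity,
                         latent = list(), envelope = list()) {
  need <- c("intensity", "ratioRedBlue", "ratioRedGreen", "sigmaIntensity",
            "diameterABD")
  miss <- setdiff(need, names(latent))
  if (length(miss))
    stop("latent must contain range(s): ", paste(miss, collapse = ", "))
  mid <- function(x) mean(latent[[x]])
  baseColor <- .colorFromTargets(mid("intensity"), mid("ratioRedBlue"),
                                 mid("ratioRedGreen"))
  new("MorphProfile", classLabel = classLabel, nCells = as.numeric(nCells),
      cellRadiusUm = as.numeric(cellRadiusUm),
      colonySpreadUm = as.numeric(colonySpreadUm),
      holeFraction = holeFraction, haloStrength = haloStrength,
      baseColor = baseColor, intensitySd = as.numeric(intensitySd),
      latent = latent, envelope = envelope)
}

#' Default morphological class profiles
#'
#' Generative profiles for the seven classes the classifier pipeline is
#' exercised on: five colonial *Microcystis* morphospecies plus the colonial
#' green alga *Micractinium* and the unicellular flagellate *Cryptomonas*.
#' Each profile's `envelope` documents the per-feature target envelope that
#' rendered-and-extracted particles of the class are expected to fall inside
#' (at `overlapScale = 0`); the latent draw ranges sit comfortably inside
#' those envelopes. The class phenotypes follow the field's morphological
#' descriptions: *Cryptomonas* is a small single cell (ABD roughly 8-13 um);
#' *Micractinium* a small multi-cell colony of intermediate brightness;
#' *M. novacekii* a large dark colony; *M. aeruginosa* a large colony with a
#' semi-transparent halo (high edge gradient and sigma intensity, long
#' perimeter); *M. ichthyoblabe* an elongated loose colony of small cells;
#' *M. smithii* a bright colony riddled with interior holes (high roughness);
#' *M. wesenbergii* a dark colony with strong grayscale texture.
#'
#' @return Named list of seven [MorphProfile-class] objects.
#' @examples
#' names(defaultProfiles())
#' @export
defaultProfiles <- function() {
  p <- list(
    MorphProfile("Cryptomonas",
      nCells = c(1, 1), cellRadiusUm = c(4.3, 6.1), colonySpreadUm = c(8.7, 12.2),
      latent = list(intensity = c(95, 115), ratioRedBlue = c(1.02, 1.18),
        ratioRedGreen = c(0.92, 1.08), sigmaIntensity = c(8, 14),
        diameterABD = c(8.7, 12.2), averageBlue = c(87.4, 108.6),
        edgeGradient = c(225.1, 238.7), perimeter = c(33.2, 46.5),
        roughness = c(1.16, 1.28), length = c(9.4, 12.8)),
      envelope = list(diameterABD = c(8.22, 12.72))),
    MorphProfile("Micractinium",
      nCells = c(5, 60), cellRadiusUm = c(2.8, 4.2), colonySpreadUm = c(18, 50),
      latent = list(intensity = c(78, 103), ratioRedBlue = c(1.0, 1.14),
        ratioRedGreen = c(0.94, 1.08), sigmaIntensity = c(12, 20),
        diameterABD = c(17.5, 38), averageBlue = c(74.2, 97.1),
        edgeGradient = c(232.7, 244.5), perimeter = c(84.8, 237.4),
        roughness = c(1.28, 1.62), length = c(24.9, 58.4)),
      envelope = list(diameterABD = c(15.85, 40.52),
        intensity = c(73.64, 105.85))),
    MorphProfile("Microcystis novacekii",
      nCells = c(40, 600), cellRadiusUm = c(2.2, 3.2),
      colonySpreadUm = c(45, 100), holeFraction = 0.05,
      latent = list(intensity = c(48, 79), ratioRedBlue = c(1.10, 1.26),
        ratioRedGreen = c(1.08, 1.22), sigmaIntensity = c(16, 27),
        diameterABD = c(40, 78), averageBlue = c(44.7, 75.5),
        edgeGradient = c(243.1, 251.9), perimeter = c(299.2, 778.5),
        roughness = c(1.7, 2.7), length = c(63.0, 113.4)),
      envelope = list(diameterABD = c(33.48, 85.69),
        intensity = c(46.45, 80.51))),
    MorphProfile("Microcystis aeruginosa",
      nCells = c(100, 1200), cellRadiusUm = c(2.0, 3.0),
      colonySpreadUm = c(65, 105), holeFraction = 0.10, haloStrength = 7,
      latent = list(intensity = c(84, 94), ratioRedBlue = c(1.22, 1.32),
        ratioRedGreen = c(1.16, 1.26), sigmaIntensity = c(10, 16),
        diameterABD = c(62, 85), averageBlue = c(88.9, 98.5),
        edgeGradient = c(114.2, 137.8), perimeter = c(706.9, 1267.4),
        roughness = c(2.8, 4.0), length = c(93.1, 123.4)),
      envelope = list(averageBlue = c(76.08, 101.01),
        edgeGradient = c(96.11, 159.87), perimeter = c(391.00, 1620.14),
        ratioRedBlue = c(1.15, 1.30), sigmaIntensity = c(23.68, 35.70))),
    MorphProfile("Microcystis ichthyoblabe",
      nCells = c(60, 600), cellRadiusUm = c(1.8, 2.6),
      colonySpreadUm = c(60, 130), holeFraction = 0.15,
      latent = list(intensity = c(80, 104), ratioRedBlue = c(1.22, 1.32),
        ratioRedGreen = c(1.13, 1.21), sigmaIntensity = c(22, 30.5),
        diameterABD = c(36, 55), averageBlue = c(70.3, 94.3),
        edgeGradient = c(235.3, 244.8), perimeter = c(415.0, 852.0),
        roughness = c(2.1, 3.7), length = c(64, 128)),
      envelope = list(averageBlue = c(72.02, 96.30),
        intensity = c(78.76, 110.43), length = c(56.85, 138.37),
        ratioRedBlue = c(1.15, 1.32), roughness = c(1.38, 4.16),
        sigmaIntensity = c(21.58, 30.97))),
    MorphProfile("Microcystis smithii",
      nCells = c(80, 900), cellRadiusUm = c(2.0, 3.0),
      colonySpreadUm = c(45, 85), holeFraction = 0.18,
      latent = list(intensity = c(95, 118), ratioRedBlue = c(1.12, 1.28),
        ratioRedGreen = c(1.17, 1.37), sigmaIntensity = c(14, 26),
        diameterABD = c(45, 65), averageBlue = c(89.4, 112.6),
        edgeGradient = c(231.5, 241.2), perimeter = c(486.3, 1031.4),
        roughness = c(2.6, 4.2), length = c(69.6, 96.4)),
      envelope = list(intensity = c(93.98, 120.00),
        ratioRedGreen = c(1.16, 1.39), roughness = c(1.58, 10.70))),
    MorphProfile("Microcystis wesenbergii",
      nCells = c(50, 700), cellRadiusUm = c(2.4, 3.4),
      colonySpreadUm = c(45, 90), holeFraction = 0.08,
      latent = list(intensity = c(71, 93), ratioRedBlue = c(1.21, 1.37),
        ratioRedGreen = c(1.16, 1.26), sigmaIntensity = c(28, 44),
        diameterABD = c(42, 70), averageBlue = c(63.0, 82.7),
        edgeGradient = c(237.7, 245.3), perimeter = c(314.4, 701.8),
        roughness = c(1.8, 2.8), length = c(67.1, 100.9)),
      envelope = list(averageBlue = c(61.31, 85.13),
        intensity = c(67.25, 98.04), ratioRedBlue = c(1.19, 1.39),
        ratioRedGreen = c(1.15, 1.27), sigmaIntensity = c(26.10, 47.12))))
  names(p) <- vapply(p, classLabel, character(1))
  p
}
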