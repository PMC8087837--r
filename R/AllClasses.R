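#' @useDynLib colonyGate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Canonical particle-property names
#'
#' The ten particle properties computed by [extractFeatures()], in their
#' canonical column order. Sizes (`diameterABD`, `length`, `perimeter`) are in
#' micrometres; signal properties (`averageBlue`, `edgeGradient`, `intensity`,
#' `sigmaIntensity`) are 8-bit grayscale/colour levels in \[0, 255\];
#' `ratioRedBlue` and `ratioRedGreen` are dimensionless channel-mean ratios;
#' `roughness` (perimeter over convex perimeter) is dimensionless and >= 1.
#'
#' @return Character vector of the ten canonical feature names.
#' @examples
#' cgFeatureNames()
#' @export
cgFeatureNames <- function() {
  c("averageBlue", "diameterABD", "edgeGradient", "intensity", "length",
    "perimeter", "ratioRedBlue", "ratioRedGreen", "roughness",
    "sigmaIntensity")
}

# display names used in on-disk feature tables (instrument-style headers)
.featureDisplay <- c(
  averageBlue    = "Average Blue",
  diameterABD    = "Diameter (ABD)",
  edgeGradient   = "Edge gradient",
  intensity      = "Intensity",
  length         = "Length",
  perimeter      = "Perimeter",
  ratioRedBlue   = "Ratio red/blue",
  ratioRedGreen  = "Ratio red/green",
  roughness      = "Roughness",
  sigmaIntensity = "Sigma intensity")

.range2 <- function(x) is.numeric(x) && length(x) == 2L && !anyNA(x) &&
  x[1] <= x[2]

#' ParticleImage: one brightfield frame holding one particle
#'
#' An 8-bit RGB raster (stored as a numeric `h x w x 3` array with values in
#' \[0, 255\]) plus the pixel calibration in micrometres per pixel. The default
#' calibration, 0.554 um/px, corresponds to a 10x imaging-flow-cytometry
#' objective.
#'
#' @slot pixels numeric array `h x w x 3`, values in \[0, 255\].
#' @slot pixelSizeUm positive scalar, micrometres per pixel.
#' @exportClass ParticleImage
setClass("ParticleImage",
  representation(pixels = "array", pixelSizeUm = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("pixels must be an h x w x 3 array")
    if (min(p) < 0 || max(p) > 255)
      return("pixel values must lie in [0, 255]")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a positive scalar")
    TRUE
  })

#' ParticleMask: segmented particle support
#'
#' Binary mask aligned with a [ParticleImage-class] raster: exactly one
#' 8-connected foreground component, interior holes preserved.
#'
#' @slot mask logical matrix.
#' @slot areaPx integer, number of TRUE pixels.
#' @slot holeCount integer, number of interior background components.
#' @exportClass ParticleMask
setClass("ParticleMask",
  representation(mask = "matrix", areaPx = "integer", holeCount = "integer"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (object@areaPx != sum(object@mask))
      return("areaPx must equal the number of TRUE mask pixels")
    if (object@areaPx < 1L) return("mask has no foreground pixel")
    TRUE
  })

#' MorphProfile: generative phenotype of one morphological class
#'
#' Parameters controlling how synthetic particles of one class are rendered:
#' colony geometry (cell count, cell radius, colony spread), interior holes
#' (drives roughness), a semi-transparent halo (drives the Sobel edge
#' gradient), base colour and grayscale texture. `latent` holds the per-class
#' draw ranges for the signal/size targets; `envelope` holds the documented
#' per-feature target envelopes that rendered-and-extracted features of this
#' class are expected to stay inside (generator self-consistency).
#'
#' @slot classLabel character scalar.
#' @slot nCells numeric length-2 range of colony cell counts.
#' @slot cellRadiusUm numeric length-2 range, cell radius in um.
#' @slot colonySpreadUm numeric length-2 range, colony spread (diameter) in um.
#' @slot holeFraction scalar in \[0,1\]: expected holes per placed cell.
#' @slot haloStrength scalar >= 0: halo ramp width in pixels (0 = sharp edge).
#' @slot baseColor numeric length-3 RGB triple in \[0,255\] at mid latent values.
#' @slot intensitySd numeric length-2 range of grayscale texture sd.
#' @slot latent named list of length-2 numeric draw ranges (at least
#'   `intensity`, `ratioRedBlue`, `ratioRedGreen`; optionally `abd`,
#'   `lengthUm`).
#' @slot envelope named list of length-2 numeric feature envelopes keyed by
#'   canonical feature names ([cgFeatureNames()]).
#' @exportClass MorphProfile
setClass("MorphProfile",
  representation(classLabel = "character", nCells = "numeric",
    cellRadiusUm = "numeric", colonySpreadUm = "numeric",
    holeFraction = "numeric", haloStrength = "numeric",
    baseColor = "numeric", intensitySd = "numeric",
    latent = "list", envelope = "list"),
  validity = function(object) {
    if (length(object@classLabel) != 1L || !nzchar(object@classLabel))
      return("classLabel must be a non-empty string")
    for (s in c("nCells", "cellRadiusUm", "colonySpreadUm", "intensitySd"))
      if (!.range2(slot(object, s)))
        return(sprintf("%s must be a numeric length-2 range with min <= max", s))
    if (object@colonySpreadUm[2] < object@cellRadiusUm[1])
      return("colonySpreadUm must be >= cellRadiusUm")
    if (object@holeFraction < 0 || object@holeFraction > 1)
      return("holeFraction must lie in [0, 1]")
    if (object@haloStrength < 0) return("haloStrength must be >= 0")
    if (length(object@baseColor) != 3L || min(object@baseColor) < 0 ||
        max(object@baseColor) > 255)
      return("baseColor must be an RGB triple in [0, 255]")
    for (nm in names(object@latent))
      if (!.range2(object@latent[[nm]]))
        return(sprintf("latent range '%s' must have min <= max", nm))
    bad <- setdiff(names(object@envelope), cgFeatureNames())
    if (length(bad))
      return(paste("unknown envelope feature(s):", paste(bad, collapse = ", ")))
    for (nm in names(object@envelope))
      if (!.range2(object@envelope[[nm]]))
        return(sprintf("envelope '%s' must have min <= max", nm))
    TRUE
  })

#' GenerationConfig: reproducible synthetic-dataset recipe
#'
#' A config plus seed fully determines every rendered image and every feature
#' table byte. `overlapScale` inflates within-class variability around each
#' latent mid-point (0 = baseline, well-separated classes). `mode` selects
#' full image rendering (`"image"`) or direct feature draws from truncated
#' normal distributions (`"table"`).
#'
#' @slot profiles list of [MorphProfile-class] with unique class names.
#' @slot nPerClass integer >= 1.
#' @slot pixelSizeUm positive scalar (default 0.554 um/px).
#' @slot imageSidePx integer, frame side in pixels.
#' @slot seed integer scalar.
#' @slot overlapScale scalar >= 0.
#' @slot mode `"image"` or `"table"`.
#' @slot threshold segmentation threshold, grayscale level (default 200).
#' @exportClass GenerationConfig
setClass("GenerationConfig",
  representation(profiles = "list", nPerClass = "integer",
    pixelSizeUm = "numeric", imageSidePx = "integer", seed = "integer",
    overlapScale = "numeric", mode = "character", threshold = "numeric"),
  validity = function(object) {
    if (!length(object@profiles) ||
        !all(vapply(object@profiles, is, logical(1), "MorphProfile")))
      return("profiles must be a non-empty list of MorphProfile")
    cls <- vapply(object@profiles, function(p) p@classLabel, character(1))
    if (anyDuplicated(cls))
      return("duplicate class names in profiles")
    if (object@nPerClass < 1L) return("nPerClass must be >= 1")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    if (object@imageSidePx < 16L) return("imageSidePx too small")
    if (object@overlapScale < 0) return("overlapScale must be >= 0")
    if (!object@mode %in% c("image", "table"))
      return("mode must be 'image' or 'table'")
    TRUE
  })

#' ParticleDataset: per-particle features, labels and sample metadata
#'
#' The unit consumed by training, classification and evaluation: one row per
#' particle with the ten canonical features, an optional true class label, and
#' sample metadata (id, mesocosm tank, sampling date; extra columns are
#' preserved).
#'
#' @slot features data.frame with the ten [cgFeatureNames()] numeric columns.
#' @slot labels character vector (NA allowed) of true class labels.
#' @slot meta data.frame with at least columns `id`, `tank`, `date`.
#' @exportClass ParticleDataset
setClass("ParticleDataset",
  representation(features = "data.frame", labels = "character",
    meta = "data.frame"),
  validity = function(object) {
    miss <- setdiff(cgFeatureNames(), names(object@features))
    if (length(miss))
      return(paste("missing feature column(s):", paste(miss, collapse = ", ")))
    n <- nrow(object@features)
    if (length(object@labels) != n)
      return("labels length must match feature rows")
    if (nrow(object@meta) != n)
      return("meta rows must match feature rows")
    miss <- setdiff(c("id", "tank", "date"), names(object@meta))
    if (length(miss))
      return(paste("missing meta column(s):", paste(miss, collapse = ", ")))
    TRUE
  })

#' RangeFilter: per-class conjunction of \[min, max\] gates
#'
#' The content of one block of an instrument-style filter file: a class name,
#' a provenance tag (training-subset size `"25"`, `"50"`, or
#' `"intersection"`), and one inclusive \[min, max\] gate per feature. A
#' particle is selected iff it satisfies every gate.
#'
#' @slot classLabel character scalar.
#' @slot gates data.frame with columns `feature`, `min`, `max`.
#' @slot provenance character scalar.
#' @exportClass RangeFilter
setClass("RangeFilter",
  representation(classLabel = "character", gates = "data.frame",
    provenance = "character"),
  validity = function(object) {
    g <- object@gates
    if (!all(c("feature", "min", "max") %in% names(g)))
      return("gates must have columns feature, min, max")
    if (anyDuplicated(g$feature))
      return("duplicate feature names within a filter")
    bad <- setdiff(g$feature, cgFeatureNames())
    if (length(bad))
      return(paste("unknown gate feature(s):", paste(bad, collapse = ", ")))
    if (nrow(g) && any(g$min > g$max))
      return("every gate must satisfy min <= max")
    TRUE
  })

#' FilterSet: one RangeFilter per class plus provenance metadata
#'
#' @slot filters named list of [RangeFilter-class], names = class names.
#' @slot metadata list; records training ids, seed and accuracy threshold so
#'   the set can be regenerated deterministically.
#' @exportClass FilterSet
setClass("FilterSet",
  representation(filters = "list", metadata = "list"),
  validity = function(object) {
    if (!length(object@filters) ||
        !all(vapply(object@filters, is, logical(1), "RangeFilter")))
      return("filters must be a non-empty list of RangeFilter")
    cls <- vapply(object@filters, function(f) f@classLabel, character(1))
    if (anyDuplicated(cls)) return("duplicate class names in filter set")
    if (!identical(names(object@filters), unname(cls)))
      return("filters list must be named by class name")
    TRUE
  })

#' ClassificationResult: per-classifier selection flags
#'
#' One logical column per class filter (TRUE iff every gate of that class is
#' satisfied, inclusive bounds), plus optional exclusive single-label
#' assignment and optional true labels.
#'
#' @slot selections logical matrix, one column per classifier class.
#' @slot exclusive character vector (length 0 when not assigned); one of the
#'   selecting classes or `"unclassified"`.
#' @slot truth character vector (length 0 when unknown).
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(selections = "matrix", exclusive = "character",
    truth = "character"),
  validity = function(object) {
    if (!is.logical(object@selections) || is.null(colnames(object@selections)))
      return("selections must be a logical matrix with class column names")
    n <- nrow(object@selections)
    if (length(object@exclusive) && length(object@exclusive) != n)
      return("exclusive labels length must match particle count")
    if (length(object@truth) && length(object@truth) != n)
      return("truth length must match particle count")
    TRUE
  })

#' GateConfusion: per-classifier confusion counts and derived rates
#'
#' Counts of particles with true class k selected by classifier c, with the
#' derived per-classifier TP/FP/TN/FN, precision, false discovery rate, true
#' positive rate and true negative rate.
#'
#' @slot counts integer matrix, rows = classifiers, columns = true classes.
#' @slot stats data.frame per classifier: TP, FP, TN, FN, precision, fdr,
#'   tpr, tnr.
#' @slot total integer, dataset size.
#' @exportClass GateConfusion
setClass("GateConfusion",
  representation(counts = "matrix", stats = "data.frame", total = "integer"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be >= 0")
    TRUE
  })

#' MetricReport: per-class and overall validation metrics
#'
#' @slot perClass data.frame: class, hellinger, balancedAccuracy, smape,
#'   precision, fdr.
#' @slot overall named list: accuracy, brayCurtis, klDivergence,
#'   hellingerMean.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(perClass = "data.frame", overall = "list"))
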