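#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("gates", function(x) standardGeneric("gates"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setGeneric("selections", function(x) standardGeneric("selections"))
#' @rdname accessors
#' @export
setGeneric("exclusiveLabels", function(x) standardGeneric("exclusiveLabels"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("gateCounts", function(x) standardGeneric("gateCounts"))
#' @rdname accessors
#' @export
setGeneric("gateStats", function(x) standardGeneric("gateStats"))

#' Accessors for colonyGate classes
#'
#' Small read-only accessors: `classLabel()` and `provenance()` on
#' [RangeFilter-class] / [MorphProfile-class], `gates()` on a filter,
#' `featureTable()`, `trueLabels()`, `sampleMeta()` and `nParticles()` on a
#' [ParticleDataset-class], `selections()` / `exclusiveLabels()` on a
#' [ClassificationResult-class], and `gateCounts()` / `gateStats()` on a
#' [GateConfusion-class].
#'
#' @param x object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
setMethod("classLabel", "MorphProfile", function(x) x@classLabel)
#' @rdname accessors
setMethod("classLabel", "RangeFilter", function(x) x@classLabel)
#' @rdname accessors
setMethod("gates", "RangeFilter", function(x) x@gates)
#' @rdname accessors
setMethod("provenance", "RangeFilter", function(x) x@provenance)
#' @rdname accessors
setMethod("featureTable", "ParticleDataset", function(x) x@features)
#' @rdname accessors
setMethod("trueLabels", "ParticleDataset", function(x) x@labels)
#' @rdname accessors
setMethod("sampleMeta", "ParticleDataset", function(x) x@meta)
#' @rdname accessors
setMethod("nParticles", "ParticleDataset", function(x) nrow(x@features))
#' @rdname accessors
setMethod("selections", "ClassificationResult", function(x) x@selections)
#' @rdname accessors
setMethod("exclusiveLabels", "ClassificationResult", function(x) x@exclusive)
#' @rdname accessors
setMethod("trueLabels", "ClassificationResult", function(x) x@truth)
#' @rdname accessors
setMethod("gateCounts", "GateConfusion", function(x) x@counts)
#' @rdname accessors
setMethod("gateStats", "GateConfusion", function(x) x@stats)

#' Subset a ParticleDataset by particle
#'
#' @param x a [ParticleDataset-class].
#' @param i integer or logical index over particles.
#' @param j,...,drop ignored.
#' @return A [ParticleDataset-class] with the selected rows.
#' @export
setMethod("[", "ParticleDataset", function(x, i, j, ..., drop = FALSE) {
  new("ParticleDataset",
      features = x@features[i, , drop = FALSE],
      labels = x@labels[i],
      meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "MorphProfile", function(object) {
  cat("MorphProfile:", object@classLabel, "\n")
  cat(sprintf("  cells %g-%g, radius %.2g-%.2g um, spread %.3g-%.3g um\n",
              object@nCells[1], object@nCells[2], object@cellRadiusUm[1],
              object@cellRadiusUm[2], object@colonySpreadUm[1],
              object@colonySpreadUm[2]))
  cat(sprintf("  holeFraction %.2f, haloStrength %.2f\n",
              object@holeFraction, object@haloStrength))
  if (length(object@envelope))
    cat("  envelope features:", paste(names(object@envelope), collapse = ", "),
        "\n")
})

setMethod("show", "ParticleDataset", function(object) {
  n <- nrow(object@features)
  cat(sprintf("ParticleDataset: %d particles, %d features\n", n,
              ncol(object@features)))
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab)) {
    tb <- table(lab)
    cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb),
                            collapse = ", "), "\n")
  } else cat("  unlabeled\n")
  cat("  samples:", length(unique(paste(object@meta$tank, object@meta$date))),
      "(tank, date) combinations\n")
})

setMethod("show", "RangeFilter", function(object) {
  cat(sprintf("RangeFilter '%s' (provenance %s), %d gate(s)\n",
              object@classLabel, object@provenance, nrow(object@gates)))
  if (nrow(object@gates))
    for (i in seq_len(nrow(object@gates)))
      cat(sprintf("  %-15s [%.4g, %.4g]\n", object@gates$feature[i],
                  object@gates$min[i], object@gates$max[i]))
})

setMethod("show", "FilterSet", function(object) {
  cat(sprintf("FilterSet: %d class filter(s)\n", length(object@filters)))
  for (f in object@filters)
    cat(sprintf("  %-20s %d gate(s) [%s]\n", f@classLabel, nrow(f@gates),
                f@provenance))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: %d particles x %d classifiers\n",
              nrow(object@selections), ncol(object@selections)))
  cat("  selected per class:",
      paste(sprintf("%s=%d", colnames(object@selections),
                    colSums(object@selections)), collapse = ", "), "\n")
  if (length(object@exclusive)) cat("  exclusive assignment present\n")
})

setMethod("show", "GateConfusion", function(object) {
  cat("GateConfusion (rows = classifiers, cols = true classes)\n")
  print(object@counts)
  print(round(object@stats[, c("precision", "fdr", "tpr", "tnr")], 3))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  print(object@perClass, digits = 4)
  ov <- object@overall
  cat(sprintf("overall: accuracy %.4f, Bray-Curtis %.4f, KLD %.4g, mean HD %.4f\n",
              ov$accuracy, ov$brayCurtis, ov$klDivergence, ov$hellingerMean))
})
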