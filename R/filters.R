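# Range-gate filter-set classifiers: fit per-class [min, max] gates from a
# small random training subset, greedily drop gates while overall accuracy
# stays above a threshold, narrow 25/50 filters into an "intersection"
# filter, and apply filters with inclusive-bound conjunction semantics.

#' Construct a RangeFilter
#'
#' @param classLabel class label.
#' @param gates data.frame with columns `feature`, `min`, `max` (features
#'   from [cgFeatureNames()], unique, `min <= max`).
#' @param provenance provenance tag, conventionally `"25"`, `"50"` or
#'   `"intersection"`.
#' @return A [RangeFilter-class].
#' @export
RangeFilter <- function(classLabel, gates, provenance = "manual") {
  gates <- data.frame(feature = as.character(gates$feature),
                      min = as.numeric(gates$min),
                      max = as.numeric(gates$max),
                      stringsAsFactors = FALSE, row.names = NULL)
  new("RangeFilter", classLabel = classLabel, gates = gates,
      provenance = as.character(provenance))
}

#' Sample a training subset for one class
#'
#' Randomly selects `n` particle indices of the given class without
#' replacement, from a per-class pool capped at the first 150 class members
#' (the representative-image pool). Deterministic for a given seed.
#'
#' @param dataset a [ParticleDataset-class] with labels.
#' @param classLabel class to sample.
#' @param n subset size, conventionally 25 or 50.
#' @param seed integer seed.
#' @param poolCap per-class pool cap (default 150).
#' @return Integer vector of dataset row indices.
#' @export
sampleTraining <- function(dataset, classLabel, n, seed, poolCap = 150L) {
  idx <- which(trueLabels(dataset) == classLabel)
  if (length(idx) > poolCap) idx <- idx[seq_len(poolCap)]
  if (length(idx) < n)
    stop("insufficient particles for class '", classLabel, "': have ",
         length(idx), ", need ", n)
  set.seed(as.integer(seed))
  sort(sample(idx, n))
}

#' Fit min/max gates from a training subset
#'
#' One gate per requested feature: the minimum and maximum of that feature
#' over the subset (the instrument's filter-dialog behaviour).
#'
#' @param dataset a [ParticleDataset-class].
#' @param ids row indices of the training subset.
#' @param classLabel class label for the resulting filter.
#' @param featureNames features to gate (default: all ten).
#' @param provenance provenance tag.
#' @return A [RangeFilter-class].
#' @export
fitRanges <- function(dataset, ids, classLabel,
                      featureNames = cgFeatureNames(),
                      provenance = as.character(length(ids))) {
  stopifnot(length(ids) >= 1)
  bad <- setdiff(featureNames, cgFeatureNames())
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  ft <- featureTable(dataset)[ids, featureNames, drop = FALSE]
  RangeFilter(classLabel,
              data.frame(feature = featureNames,
                         min = vapply(ft, min, numeric(1)),
                         max = vapply(ft, max, numeric(1))),
              provenance)
}

# selection flags of one filter on a feature table (inclusive bounds)
.selectBy <- function(filter, features) {
  g <- filter@gates
  miss <- setdiff(g$feature, names(features))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  sel <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(g))) {
    v <- features[[g$feature[i]]]
    sel <- sel & v >= g$min[i] & v <= g$max[i]
  }
  sel
}

# overall accuracy of a one-vs-rest filter on a labeled feature table
.filterAccuracy <- function(filter, features, labels) {
  sel <- .selectBy(filter, features)
  pos <- labels == filter@classLabel
  (sum(sel & pos) + sum(!sel & !pos)) / length(labels)
}

#' Greedy backward gate reduction under an accuracy floor
#'
#' Repeatedly removes the gate whose removal yields the highest overall
#' one-vs-rest accuracy on the labeled data, stopping before any removal
#' would drop accuracy to `accuracyThreshold` or below. Ties are broken by
#' canonical feature order. Returns the smallest gate set visited with
#' accuracy above the threshold. If the input filter is already at or below
#' the threshold it is returned unchanged with a warning.
#'
#' @param filter a [RangeFilter-class].
#' @param dataset a labeled [ParticleDataset-class] containing positives and
#'   negatives for the filter's class.
#' @param accuracyThreshold stopping floor (default 0.75).
#' @return A reduced [RangeFilter-class].
#' @export
reduceFeatures <- function(filter, dataset, accuracyThreshold = 0.75) {
  features <- featureTable(dataset)
  labels <- trueLabels(dataset)
  if (!any(labels == filter@classLabel) || all(labels == filter@classLabel))
    stop("labeled data must contain positives and negatives for class '",
         filter@classLabel, "'")
  current <- filter
  if (.filterAccuracy(current, features, labels) <= accuracyThreshold) {
    warning("initial filter accuracy already <= ", accuracyThreshold,
            "; returning input unchanged")
    return(current)
  }
  canon <- cgFeatureNames()
  repeat {
    g <- current@gates
    if (nrow(g) <= 0L) break
    accs <- vapply(seq_len(nrow(g)), function(i) {
      cand <- current
      cand@gates <- g[-i, , drop = FALSE]
      if (nrow(cand@gates) == 0L) {
        # gateless filter selects everything
        mean(labels == filter@classLabel)
      } else .filterAccuracy(cand, features, labels)
    }, numeric(1))
    best <- max(accs)
    if (best <= accuracyThreshold) break
    drop <- which(accs == best)
    drop <- drop[order(match(g$feature[drop], canon))][1]
    current@gates <- g[-drop, , drop = FALSE]
    if (nrow(current@gates) == 0L) break
  }
  rownames(current@gates) <- NULL
  current
}

#' Intersect the 25- and 50-image filters of one class
#'
#' For features gated in both filters the narrowed gate takes the highest
#' minimum and the lowest maximum; a feature present in only one filter
#' carries its gate over unchanged. An empty narrowed range (min > max) is an
#' error.
#'
#' @param f25,f50 [RangeFilter-class] objects for the same class.
#' @return A [RangeFilter-class] with provenance `"intersection"`.
#' @examples
#' a <- RangeFilter("c", data.frame(feature = "intensity", min = 1, max = 5), "25")
#' b <- RangeFilter("c", data.frame(feature = "intensity", min = 2, max = 7), "50")
#' gates(intersectFilters(a, b))
#' @export
intersectFilters <- function(f25, f50) {
  if (f25@classLabel != f50@classLabel)
    stop("class mismatch: '", f25@classLabel, "' vs '", f50@classLabel, "'")
  feats <- union(f25@gates$feature, f50@gates$feature)
  g25 <- f25@gates[match(feats, f25@gates$feature), ]
  g50 <- f50@gates[match(feats, f50@gates$feature), ]
  mn <- pmax(g25$min, g50$min, na.rm = TRUE)
  mx <- pmin(g25$max, g50$max, na.rm = TRUE)
  if (any(mn > mx))
    stop("empty intersection for feature(s): ",
         paste(feats[mn > mx], collapse = ", "))
  RangeFilter(f25@classLabel,
              data.frame(feature = feats, min = mn, max = mx),
              "intersection")
}

#' Build a FilterSet for several classes
#'
#' For each class: sample a training subset of size `n`, fit gates over
#' `featureNames`, and (optionally) reduce them greedily against the full
#' labeled dataset. Metadata records the subset ids, seed and threshold so
#' the set regenerates deterministically.
#'
#' @param dataset labeled [ParticleDataset-class].
#' @param classNames classes to build filters for (default: all labels).
#' @param n training subset size per class (25 or 50).
#' @param seed integer seed (one shared stream; per-class seeds derived by
#'   offset).
#' @param featureNames starting gate set (default: all ten features).
#' @param reduce logical: apply [reduceFeatures()] (default TRUE).
#' @param accuracyThreshold reduction floor.
#' @return A [FilterSet-class].
#' @export
trainFilterSet <- function(dataset, classNames = NULL, n = 25, seed = 1L,
                           featureNames = cgFeatureNames(), reduce = TRUE,
                           accuracyThreshold = 0.75) {
  if (is.null(classNames))
    classNames <- sort(unique(stats::na.omit(trueLabels(dataset))))
  filters <- list()
  trainIds <- list()
  for (k in seq_along(classNames)) {
    cl <- classNames[k]
    ids <- sampleTraining(dataset, cl, n, seed + k - 1L)
    f <- fitRanges(dataset, ids, cl, featureNames, as.character(n))
    if (reduce) f <- reduceFeatures(f, dataset, accuracyThreshold)
    filters[[cl]] <- f
    trainIds[[cl]] <- ids
  }
  new("FilterSet", filters = filters,
      metadata = list(trainIds = trainIds, seed = seed, n = n,
                      accuracyThreshold = accuracyThreshold,
                      featureNames = featureNames, reduce = reduce))
}

#' Intersect two FilterSets class-wise
#'
#' @param fs25,fs50 [FilterSet-class] objects over the same classes.
#' @return A [FilterSet-class] of intersection filters.
#' @export
intersectFilterSets <- function(fs25, fs50) {
  cls <- names(fs25@filters)
  if (!setequal(cls, names(fs50@filters)))
    stop("filter sets cover different classes")
  filters <- lapply(cls, function(cl)
    intersectFilters(fs25@filters[[cl]], fs50@filters[[cl]]))
  names(filters) <- cls
  new("FilterSet", filters = filters,
      metadata = list(from = list(fs25@metadata, fs50@metadata)))
}

#' Training ids of a FilterSet
#'
#' Row indices used to fit each class filter; downstream evaluation excludes
#' them from the test split.
#'
#' @param filterSet a [FilterSet-class].
#' @return Named list of integer vectors (may be empty for intersection
#'   sets built from two parents, whose union is returned).
#' @export
trainingIds <- function(filterSet) {
  md <- filterSet@metadata
  if (!is.null(md$trainIds)) return(md$trainIds)
  if (!is.null(md$from)) {
    ids <- lapply(md$from, function(m) m$trainIds)
    ids <- ids[!vapply(ids, is.null, logical(1))]
    if (length(ids)) {
      cls <- names(ids[[1]])
      out <- lapply(cls, function(cl)
        sort(unique(unlist(lapply(ids, `[[`, cl)))))
      names(out) <- cls
      return(out)
    }
  }
  list()
}

#' Apply a FilterSet to a dataset
#'
#' Per-classifier mode sets one boolean flag per class filter (all gates
#' satisfied, inclusive bounds). Exclusive mode additionally assigns each
#' particle the first selecting class in `priority` order, or
#' `"unclassified"` when no filter selects it.
#'
#' @param filterSet a [FilterSet-class].
#' @param dataset a [ParticleDataset-class].
#' @param mode `"perclass"` or `"exclusive"`.
#' @param priority class evaluation order for exclusive mode (default: the
#'   filter-set order).
#' @return A [ClassificationResult-class].
#' @export
applyFilters <- function(filterSet, dataset, mode = c("perclass", "exclusive"),
                         priority = names(filterSet@filters)) {
  mode <- match.arg(mode)
  features <- featureTable(dataset)
  sel <- vapply(filterSet@filters, .selectBy, logical(nrow(features)),
                features = features)
  if (!is.matrix(sel)) sel <- matrix(sel, nrow = 1L,
                                     dimnames = list(NULL, names(filterSet@filters)))
  exclusive <- character(0)
  if (mode == "exclusive") {
    stopifnot(setequal(priority, colnames(sel)))
    exclusive <- rep("unclassified", nrow(sel))
    for (cl in rev(priority)) exclusive[sel[, cl]] <- cl
    # rev + overwrite means earlier priority classes win
  }
  truth <- trueLabels(dataset)
  new("ClassificationResult", selections = sel, exclusive = exclusive,
      truth = if (all(is.na(truth))) character(0) else truth)
}

#' Write / read filter sets as plain structured text
#'
#' One block per class: `class:` and `provenance:` lines followed by one
#' `feature min max` line per gate (full double precision); blocks separated
#' by blank lines. The format round-trips bit-exactly.
#'
#' @param filterSet a [FilterSet-class].
#' @param path file path.
#' @return `writeFilterSet` returns `path` invisibly; `readFilterSet`
#'   returns a [FilterSet-class].
#' @export
writeFilterSet <- function(filterSet, path) {
  lines <- character(0)
  for (f in filterSet@filters) {
    lines <- c(lines, paste0("class: ", f@classLabel),
               paste0("provenance: ", f@provenance))
    for (i in seq_len(nrow(f@gates)))
      lines <- c(lines, sprintf("%s %.17g %.17g", f@gates$feature[i],
                                f@gates$min[i], f@gates$max[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFilterSet
#' @export
readFilterSet <- function(path) {
  lines <- readLines(path)
  filters <- list()
  cl <- NULL; prov <- NULL; rows <- list()
  flush <- function() {
    if (is.null(cl)) return()
    g <- if (length(rows)) do.call(rbind, rows)
         else data.frame(feature = character(0), min = numeric(0),
                         max = numeric(0))
    filters[[cl]] <<- RangeFilter(cl, g, prov)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "class:")) {
      flush(); rows <- list()
      cl <- trimws(sub("^class:", "", ln)); prov <- "manual"
    } else if (startsWith(ln, "provenance:")) {
      prov <- trimws(sub("^provenance:", "", ln))
    } else {
      # feature names contain no spaces; min and max are the last two fields
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 3L) stop("malformed gate line: ", ln)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = parts[1], min = as.numeric(parts[2]),
        max = as.numeric(parts[3]), stringsAsFactors = FALSE)
    }
  }
  flush()
  new("FilterSet", filters = filters, metadata = list(source = path))
}
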