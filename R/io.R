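# Feature-table I/O, seasonal abundance aggregation and the end-to-end
# pipeline driver. On-disk feature tables use instrument-style column
# headers ("Average Blue", "Diameter (ABD)", ...; sizes in micrometres) plus
# id, class, tank, date; unknown columns survive a round trip.

#' Write / read a feature table CSV
#'
#' Columns: the ten particle properties under their display names, plus
#' `id`, `class`, `tank`, `date` and any extra metadata columns. Values are
#' written with full double precision so that a write/read round trip
#' reproduces the dataset exactly.
#'
#' @param dataset a [ParticleDataset-class].
#' @param path CSV path.
#' @return `writeFeatureTable` returns `path` invisibly;
#'   `readFeatureTable` returns a [ParticleDataset-class].
#' @export
writeFeatureTable <- function(dataset, path) {
  ft <- featureTable(dataset)
  names(ft) <- .featureDisplay[names(ft)]
  meta <- sampleMeta(dataset)
  out <- cbind(id = meta$id, class = trueLabels(dataset),
               tank = meta$tank, date = meta$date,
               meta[, setdiff(names(meta), c("id", "tank", "date")),
                    drop = FALSE],
               ft)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(unname(.featureDisplay), names(raw))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  features <- raw[, unname(.featureDisplay), drop = FALSE]
  for (j in seq_along(features)) {
    v <- suppressWarnings(as.numeric(features[[j]]))
    bad <- which(is.na(v) & !is.na(features[[j]]))
    if (length(bad))
      stop("unparseable numeric cell in column '", names(features)[j],
           "', row ", bad[1])
    features[[j]] <- v
  }
  names(features) <- names(.featureDisplay)
  n <- nrow(raw)
  labels <- if ("class" %in% names(raw)) as.character(raw$class)
            else rep(NA_character_, n)
  meta <- data.frame(
    id = if ("id" %in% names(raw)) as.character(raw$id)
         else sprintf("p%06d", seq_len(n)),
    tank = if ("tank" %in% names(raw)) as.character(raw$tank)
           else rep(NA_character_, n),
    date = if ("date" %in% names(raw)) .canonDate(as.character(raw$date))
           else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), c(unname(.featureDisplay),
                                 "id", "class", "tank", "date"))
  if (length(extra)) meta <- cbind(meta, raw[, extra, drop = FALSE])
  .newDataset(features, labels, meta)
}

#' Seasonal abundance table from an exclusive classification
#'
#' Aggregates exclusive class assignments per (tank, date) sample: counts
#' and percentages over the colonial classes. Labels in `excludeClasses`
#' (residual bins such as `"unclassified"`, `"Membrane"`, `"Undefined"`) are
#' counted separately and excluded from the percentage denominator. Rows are
#' sorted by tank then date. A sample with zero colonial particles keeps its
#' zero counts and flags its percentages as undefined (NaN).
#'
#' @param result a [ClassificationResult-class] with exclusive labels.
#' @param meta data.frame with `tank` and `date` per particle (e.g.
#'   [sampleMeta()] of the classified dataset).
#' @param excludeClasses labels excluded from the colonial denominator.
#' @return data.frame: tank, date, class, count, percent, plus per-sample
#'   `excluded` count (residual particles).
#' @export
abundanceTimeseries <- function(result, meta,
                                excludeClasses = c("unclassified",
                                                   "Membrane", "Undefined")) {
  lab <- exclusiveLabels(result)
  if (!length(lab))
    stop("exclusive-mode classification labels are required")
  stopifnot(nrow(meta) == length(lab))
  tank <- as.character(meta$tank)
  date <- .canonDate(as.character(meta$date))
  classes <- setdiff(colnames(selections(result)), excludeClasses)
  samples <- unique(data.frame(tank = tank, date = date,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$tank, samples$date), , drop = FALSE]
  out <- list()
  for (s in seq_len(nrow(samples))) {
    inS <- tank == samples$tank[s] & date == samples$date[s]
    colonial <- inS & !(lab %in% excludeClasses)
    denom <- sum(colonial)
    counts <- vapply(classes, function(cl) sum(lab[inS] == cl), numeric(1))
    out[[s]] <- data.frame(
      tank = samples$tank[s], date = samples$date[s], class = classes,
      count = counts,
      percent = if (denom > 0) 100 * counts / denom else rep(NaN, length(classes)),
      excluded = sum(inS & lab %in% excludeClasses),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' generate -> extract -> train ("25" and "50") -> intersect -> classify ->
#' evaluate -> seasonal abundance, writing every artifact plus a structured
#' log under `outDir`. Training subsets are excluded from the evaluation
#' split. Rerunning with the same config reproduces every artifact byte.
#'
#' @param config a [GenerationConfig-class] (or a YAML path readable by
#'   [readGenerationConfig()]).
#' @param outDir output directory.
#' @param classNames classes to build filters for (default: all generated).
#' @param featureNames starting gate features (default: all ten).
#' @param accuracyThreshold gate-reduction floor (default 0.75).
#' @param writeImages also write the rendered frames (image mode only).
#' @return Invisibly, a list with the dataset, the three filter sets, the
#'   test-split classification results, the [MetricReport-class] per filter
#'   set, and the abundance table.
#' @export
runPipeline <- function(config, outDir, classNames = NULL,
                        featureNames = cgFeatureNames(),
                        accuracyThreshold = 0.75, writeImages = FALSE) {
  if (is.character(config)) config <- readGenerationConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline.log")
  logLine <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
    cat(msg, "\n", file = logPath, append = TRUE, sep = "")
  }
  cat("", file = logPath)
  stage <- "generate"
  res <- tryCatch({
    logLine("config", sprintf("seed=%d nPerClass=%d mode=%s overlapScale=%g ",
                              config@seed, config@nPerClass, config@mode,
                              config@overlapScale),
            sprintf("threshold=%g accuracyThreshold=%g pixelSizeUm=%g",
                    config@threshold, accuracyThreshold, config@pixelSizeUm))
    dataset <- generateDataset(config,
                               outDir = if (writeImages) outDir else NULL)
    logLine(stage, sprintf("particles=%d classes=%d", nParticles(dataset),
                           length(unique(trueLabels(dataset)))))
    writeFeatureTable(dataset, file.path(outDir, "features.csv"))

    stage <- "train"
    sets <- list()
    for (n in c(25, 50)) {
      fs <- trainFilterSet(dataset, classNames = classNames, n = n,
                           seed = config@seed, featureNames = featureNames,
                           accuracyThreshold = accuracyThreshold)
      writeFilterSet(fs, file.path(outDir, sprintf("filters_%d.txt", n)))
      logLine(stage, sprintf("n=%d gates=%s", n,
        paste(vapply(fs@filters, function(f) nrow(f@gates), numeric(1)),
              collapse = ",")))
      sets[[as.character(n)]] <- fs
    }

    stage <- "intersect"
    fsInt <- intersectFilterSets(sets[["25"]], sets[["50"]])
    writeFilterSet(fsInt, file.path(outDir, "filters_intersection.txt"))
    sets[["intersection"]] <- fsInt

    stage <- "classify"
    exclude <- sort(unique(unlist(lapply(sets, trainingIds))))
    testIds <- setdiff(seq_len(nParticles(dataset)), exclude)
    testSet <- dataset[testIds]
    trainSet <- dataset[exclude]
    results <- lapply(sets, applyFilters, dataset = testSet)
    logLine(stage, sprintf("test=%d train(excluded)=%d", length(testIds),
                           length(exclude)))

    stage <- "evaluate"
    reports <- lapply(names(sets), function(nm)
      evaluateFilterSet(results[[nm]],
                        trainResult = applyFilters(sets[[nm]], trainSet),
                        klPseudocount = 0.5))
    names(reports) <- names(sets)
    for (nm in names(reports))
      writeMetricReport(reports[[nm]],
                        file.path(outDir, sprintf("metrics_%s.csv", nm)))
    logLine(stage, sprintf("intersection meanBA=%.3f",
      mean(reports[["intersection"]]@perClass$balancedAccuracy)))

    stage <- "timeseries"
    excl <- applyFilters(fsInt, testSet, mode = "exclusive")
    abundance <- abundanceTimeseries(excl, sampleMeta(testSet))
    utils::write.csv(abundance, file.path(outDir, "abundance.csv"),
                     row.names = FALSE)
    logLine(stage, sprintf("samples=%d",
                           nrow(unique(abundance[, c("tank", "date")]))))
    list(dataset = dataset, filterSets = sets, results = results,
         reports = reports, abundance = abundance)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  invisible(res)
}
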