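# Validation metrics for range-gate classification: overall accuracy,
# per-classifier confusion counts with precision and false discovery rate,
# balanced accuracy, Hellinger distance between dataset compositions, SMAPE
# per class, Bray-Curtis dissimilarity and Kullback-Leibler divergence.

#' Overall accuracy
#'
#' `(TN + TP) / total` — the rule used to decide when gate reduction must
#' stop.
#'
#' @param tp,tn true positive / true negative counts.
#' @param total total number of results (> 0).
#' @return Accuracy in \[0, 1\].
#' @examples
#' gateAccuracy(3, 5, 10)
#' @export
gateAccuracy <- function(tp, tn, total) {
  stopifnot(total > 0, tp + tn <= total, tp >= 0, tn >= 0)
  (tn + tp) / total
}

#' Per-classifier confusion counts
#'
#' Cross-tabulates each class filter's selections against the true labels:
#' `counts[c, k]` is the number of particles with true label `k` selected by
#' classifier `c`. Derived per-classifier statistics: TP, FP, TN, FN,
#' precision = TP/(TP+FP), false discovery rate = FP/(TP+FP), true positive
#' rate and true negative rate.
#'
#' @param result a [ClassificationResult-class] carrying true labels (or
#'   pass `truth`).
#' @param truth optional character vector of true labels.
#' @return A [GateConfusion-class].
#' @export
confusionCounts <- function(result, truth = trueLabels(result)) {
  sel <- selections(result)
  if (!length(truth)) stop("true labels are required")
  stopifnot(length(truth) == nrow(sel))
  classes <- colnames(sel)
  trueCls <- sort(unique(truth))
  counts <- matrix(0L, length(classes), length(trueCls),
                   dimnames = list(classifier = classes, true = trueCls))
  for (c in classes) for (k in trueCls)
    counts[c, k] <- sum(sel[, c] & truth == k)
  n <- length(truth)
  stats <- do.call(rbind, lapply(classes, function(c) {
    pos <- truth == c
    tp <- sum(sel[, c] & pos); fp <- sum(sel[, c] & !pos)
    fn <- sum(!sel[, c] & pos); tn <- sum(!sel[, c] & !pos)
    data.frame(class = c, TP = tp, FP = fp, TN = tn, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
               tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  rownames(stats) <- classes
  new("GateConfusion", counts = counts, stats = stats, total = n)
}

#' Balanced accuracy of one classifier
#'
#' Mean of the true positive rate and the true negative rate; robust to
#' class imbalance.
#'
#' @param confusion a [GateConfusion-class].
#' @param classLabel classifier to report.
#' @return `(TPR + TNR) / 2`.
#' @export
balancedAccuracy <- function(confusion, classLabel) {
  st <- gateStats(confusion)
  if (!classLabel %in% rownames(st)) stop("unknown classifier: ", classLabel)
  row <- st[classLabel, ]
  if (row$TP + row$FN == 0 || row$TN + row$FP == 0)
    stop("degenerate class '", classLabel, "': needs >= 1 positive and >= 1 negative")
  (row$tpr + row$tnr) / 2
}

.asCountMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (any(x < 0)) stop("counts must be >= 0")
  x
}

#' Hellinger distance between two binned datasets
#'
#' For each filter set (row) `f`, the distance between the bin proportions
#' of the dataset `X` and the training set `T`:
#' `HD_f = (1/sqrt(2)) * sqrt(sum_k (sqrt(X_fk/X) - sqrt(T_fk/T))^2)`,
#' where `X` and `T` are the grand totals. The `1/sqrt(2)` normalisation
#' maps disjoint support to 1; identical (proportional) compositions give 0.
#' The overall value is the mean of the per-row distances.
#'
#' @param x,t numeric count matrices (filter sets x bins) or vectors (one
#'   filter set).
#' @return List with `perSet` (one HD per row, each in \[0, 1\]) and `mean`.
#' @examples
#' hellingerDistance(c(2, 4, 6), c(1, 2, 3))$mean   # proportional -> 0
#' hellingerDistance(c(5, 0), c(0, 7))$mean         # disjoint -> 1
#' @export
hellingerDistance <- function(x, t) {
  x <- .asCountMatrix(x); t <- .asCountMatrix(t)
  stopifnot(identical(dim(x), dim(t)))
  totX <- sum(x); totT <- sum(t)
  if (totX <= 0 || totT <= 0) stop("zero total counts")
  perSet <- vapply(seq_len(nrow(x)), function(f)
    sqrt(sum((sqrt(x[f, ] / totX) - sqrt(t[f, ] / totT))^2)) / sqrt(2),
    numeric(1))
  list(perSet = perSet, mean = mean(perSet))
}

#' Symmetric mean absolute percentage error per class
#'
#' For one class: the mean over filter sets of `|X - X'| / (X + X')`,
#' reported as a percentage. Terms with `X = X' = 0` contribute 0.
#'
#' @param actual,forecast numeric vectors over filter sets (one value per
#'   filter set) of actual and forecast counts for the class.
#' @return SMAPE in percent, in \[0, 100\].
#' @examples
#' smapePerClass(10, 30)   # 50
#' @export
smapePerClass <- function(actual, forecast) {
  stopifnot(length(actual) == length(forecast),
            all(actual + forecast >= 0))
  terms <- ifelse(actual + forecast == 0, 0,
                  abs(actual - forecast) / (actual + forecast))
  100 * mean(terms)
}

#' Bray-Curtis dissimilarity
#'
#' `sum_k |X_k - X'_k| / sum_k (X_k + X'_k)`: 0 iff the forecast counts are
#' identical to the actual counts, 1 for disjoint support.
#'
#' @param actual,forecast nonnegative count vectors over bins.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' brayCurtis(c(10, 30), c(20, 20))   # 0.25
#' @export
brayCurtis <- function(actual, forecast) {
  stopifnot(length(actual) == length(forecast))
  tot <- sum(actual + forecast)
  if (tot <= 0) stop("all-zero inputs")
  sum(abs(actual - forecast)) / tot
}

#' Kullback-Leibler divergence of forecast from actual composition
#'
#' Normalises both count vectors to probabilities and returns
#' `sum_k p_k (log p_k - log q_k)`. Bins with `X_k = 0` contribute 0. A bin
#' with actual mass but zero forecast mass is an error unless a pseudo-count
#' is supplied (added to every forecast bin). Natural log by default.
#'
#' @param actual,forecast nonnegative count vectors over bins.
#' @param base log base (default `exp(1)`).
#' @param pseudocount optional value added to every forecast bin to avoid
#'   infinite divergence.
#' @return Divergence >= 0 (Gibbs' inequality).
#' @examples
#' klDivergence(c(1, 0), c(0.5, 0.5))   # log(2)
#' @export
klDivergence <- function(actual, forecast, base = exp(1),
                         pseudocount = NULL) {
  stopifnot(length(actual) == length(forecast),
            all(actual >= 0), all(forecast >= 0))
  if (!is.null(pseudocount)) forecast <- forecast + pseudocount
  if (sum(actual) <= 0 || sum(forecast) <= 0) stop("zero total counts")
  p <- actual / sum(actual)
  q <- forecast / sum(forecast)
  if (any(p > 0 & q == 0))
    stop("infinite divergence: actual mass in a bin with zero forecast ",
         "mass (supply a pseudocount to regularise)")
  keep <- p > 0
  sum(p[keep] * (log(p[keep], base = base) - log(q[keep], base = base)))
}

#' Evaluate a filter set against true labels
#'
#' Produces the standard evaluation report: per class, the precision and
#' false discovery rate, balanced accuracy, Hellinger distance between the
#' classifier's selection composition on the training split and on the test
#' split (a dataset-shift indicator; requires `trainResult`), and SMAPE
#' between actual and selected counts; overall, the one-vs-rest accuracy over
#' all one-vs-rest decisions, Bray-Curtis dissimilarity and Kullback-Leibler
#' divergence between the actual class counts and the per-classifier
#' selected counts.
#'
#' @param result [ClassificationResult-class] on the test split (with true
#'   labels).
#' @param trainResult optional [ClassificationResult-class] on the training
#'   split, for the Hellinger columns.
#' @param klPseudocount passed to [klDivergence()].
#' @return A [MetricReport-class].
#' @export
evaluateFilterSet <- function(result, trainResult = NULL,
                              klPseudocount = NULL) {
  truth <- trueLabels(result)
  if (!length(truth)) stop("true labels are required")
  cm <- confusionCounts(result)
  st <- gateStats(cm)
  classes <- rownames(st)
  cmTrain <- if (!is.null(trainResult)) confusionCounts(trainResult)
  hd <- rep(NA_real_, length(classes))
  if (!is.null(cmTrain)) {
    common <- intersect(colnames(gateCounts(cm)), colnames(gateCounts(cmTrain)))
    for (i in seq_along(classes)) {
      xf <- gateCounts(cm)[classes[i], common]
      tf <- gateCounts(cmTrain)[classes[i], common]
      if (sum(xf) > 0 && sum(tf) > 0)
        hd[i] <- hellingerDistance(xf, tf)$mean
    }
  }
  actual <- vapply(classes, function(c) sum(truth == c), numeric(1))
  selected <- vapply(classes, function(c) sum(selections(result)[, c]),
                     numeric(1))
  perClass <- data.frame(
    class = classes,
    hellinger = hd,
    balancedAccuracy = (st$tpr + st$tnr) / 2,
    smape = mapply(smapePerClass, actual, selected),
    precision = st$precision,
    fdr = st$fdr,
    row.names = NULL)
  overall <- list(
    accuracy = sum(st$TP + st$TN) / (length(truth) * length(classes)),
    brayCurtis = brayCurtis(actual, selected),
    klDivergence = klDivergence(actual, selected,
                                pseudocount = klPseudocount),
    hellingerMean = if (all(is.na(hd))) NA_real_ else mean(hd, na.rm = TRUE))
  new("MetricReport", perClass = perClass, overall = overall)
}

#' Write a MetricReport as CSV
#'
#' One row per class with the report columns (filter set, Hellinger
#' distance, balanced accuracy %, SMAPE %, Bray-Curtis, KLD); the overall
#' metrics are repeated on every row, as in a summary table.
#'
#' @param report a [MetricReport-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  pc <- report@perClass
  out <- data.frame(
    `filter set` = pc$class,
    `Hellinger distance` = pc$hellinger,
    `Balanced accuracy (%)` = 100 * pc$balancedAccuracy,
    `SMAPE (%)` = pc$smape,
    `Bray-Curtis dissimilarity` = report@overall$brayCurtis,
    `Kullback-Leibler Divergence` = report@overall$klDivergence,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
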