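#' Hamming distance between label vectors
#'
#' Number of positions where the true and predicted label vectors
#' disagree; for matrices, one distance per row. The usual aggregate is
#' the mean over a test set (the average number of missed labels per
#' window).
#'
#' @param y,yHat binary vectors of equal length, or matrices of equal
#'   shape.
#' @return integer distance(s).
#' @export
hammingDistance <- function(y, yHat) {
  if (is.null(dim(y))) {
    if (length(y) != length(yHat)) stop("label vectors differ in length")
    return(sum(y != yHat))
  }
  if (!all(dim(y) == dim(yHat))) stop("label matrices differ in shape")
  rowSums(y != yHat)
}

#' Exact accuracy of multi-label predictions
#'
#' Fraction of samples whose predicted label vector matches the truth in
#' every position; with `ignoreLast = TRUE` the final (other-facilities)
#' label is excluded from the comparison, giving the top-facilities
#' variant.
#'
#' @param y,yHat binary matrices (samples x labels).
#' @param ignoreLast drop the last label before comparing.
#' @return a fraction in `[0, 1]`.
#' @export
exactAccuracy <- function(y, yHat, ignoreLast = FALSE) {
  if (!all(dim(y) == dim(yHat))) stop("label matrices differ in shape")
  if (nrow(y) == 0L) stop("empty evaluation set")
  if (ignoreLast) {
    y <- y[, -ncol(y), drop = FALSE]
    yHat <- yHat[, -ncol(yHat), drop = FALSE]
  }
  mean(rowSums(y != yHat) == 0L)
}

#' Per-label confusion counts
#'
#' @param y,yHat binary matrices (samples x labels).
#' @return data.frame with one row per label: TP, FP, TN, FN.
#' @export
confusionCounts <- function(y, yHat) {
  if (!all(dim(y) == dim(yHat))) stop("label matrices differ in shape")
  data.frame(label = seq_len(ncol(y)),
             TP = colSums(y == 1 & yHat == 1),
             FP = colSums(y == 0 & yHat == 1),
             TN = colSums(y == 0 & yHat == 0),
             FN = colSums(y == 1 & yHat == 0))
}

#' Area under the ROC curve (rank statistic)
#'
#' Probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted half — the Mann-Whitney form of
#' the AUC, computed from mid-ranks.
#'
#' @param scores numeric vector of continuous scores.
#' @param labels binary vector.
#' @return the AUC, or `NA` if the label is constant.
#' @export
aucScore <- function(scores, labels) {
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Per-label evaluation metrics
#'
#' Accuracy, precision, recall and F1 from the per-label confusion
#' counts, plus the AUC computed from the continuous (pre-threshold)
#' scores. Undefined precision (no predicted positives) is reported as 0
#' and flagged; AUC for a constant label is `NA` and flagged.
#'
#' @param y,yHat binary matrices (samples x labels).
#' @param scores continuous score matrix of the same shape.
#' @return data.frame (one row per label) with attribute `flags`.
#' @export
perLabelMetrics <- function(y, yHat, scores) {
  cc <- confusionCounts(y, yHat)
  flags <- character(0)
  precision <- ifelse(cc$TP + cc$FP > 0, cc$TP / (cc$TP + cc$FP), 0)
  for (j in which(cc$TP + cc$FP == 0))
    flags <- c(flags, sprintf("label %d: no predicted positives", j))
  recall <- ifelse(cc$TP + cc$FN > 0, cc$TP / (cc$TP + cc$FN), NA_real_)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  auc <- vapply(seq_len(ncol(y)), function(j)
    aucScore(scores[, j], y[, j]), 0)
  for (j in which(is.na(auc)))
    flags <- c(flags, sprintf("label %d: constant, AUC undefined", j))
  out <- data.frame(
    label = cc$label,
    accuracy = (cc$TP + cc$TN) / (cc$TP + cc$FP + cc$TN + cc$FN),
    precision = precision, recall = recall, f1 = f1, auc = auc)
  attr(out, "flags") <- flags
  out
}

#' Overall (pooled and averaged) metrics
#'
#' Micro-averaged precision, recall and F1 pool the confusion counts
#' over all labels; the micro AUC pools every (score, label) pair into
#' one ranking. Macro variants (plain means over labels, NA-removed for
#' AUC) are reported alongside so the averaging convention is always
#' visible.
#'
#' @param y,yHat binary matrices (samples x labels).
#' @param scores continuous score matrix of the same shape.
#' @return named numeric vector with elements `microPrecision`,
#'   `microRecall`, `microF1`, `microAUC`, `macroPrecision`,
#'   `macroRecall`, `macroF1`, `macroAUC`.
#' @export
overallMetrics <- function(y, yHat, scores) {
  cc <- confusionCounts(y, yHat)
  TP <- sum(cc$TP); FP <- sum(cc$FP); FN <- sum(cc$FN)
  microP <- if (TP + FP > 0) TP / (TP + FP) else 0
  microR <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  microF1 <- if (microP + microR > 0) 2 * microP * microR /
    (microP + microR) else 0
  per <- perLabelMetrics(y, yHat, scores)
  c(microPrecision = microP, microRecall = microR, microF1 = microF1,
    microAUC = aucScore(as.vector(scores), as.vector(y)),
    macroPrecision = mean(per$precision),
    macroRecall = mean(per$recall, na.rm = TRUE),
    macroF1 = mean(per$f1),
    macroAUC = mean(per$auc, na.rm = TRUE))
}

#' First-access prediction accuracy
#'
#' For each top facility `j`, restricts to test windows where the
#' patient had no appointment at facility `j` during the 52 input weeks
#' (raw counts, column `j` all zero) yet attended it in the forecast
#' period (`y_j = 1`), and reports the fraction of these first accesses
#' the model predicted. Every window in the subset is a true positive
#' or false negative by construction, so this is the recall on first
#' accesses.
#'
#' @param ws the [WindowSet-class] the predictions refer to (raw
#'   counts).
#' @param yHat binary prediction matrix for (a subset of) `ws`.
#' @param idx window indices of `yHat`'s rows within `ws`.
#' @return data.frame per facility: subset size `n`, `accuracy` (`NA`
#'   and flagged when the subset is empty).
#' @export
firstAccessAccuracy <- function(ws, yHat,
                                idx = seq_len(nWindows(ws))) {
  nTop <- length(ws@catalog@topFacilities)
  res <- lapply(seq_len(nTop), function(j) {
    colJ <- matrix(ws@F[, j, idx], nrow = dim(ws@F)[1])
    neverVisited <- colSums(colJ) == 0
    sub <- which(neverVisited & ws@y[idx, j] == 1)
    data.frame(facility = j, n = length(sub),
               accuracy = if (length(sub)) mean(yHat[sub, j] == 1)
               else NA_real_)
  })
  out <- do.call(rbind, res)
  attr(out, "flags") <- sprintf("facility %d: no first accesses",
                                out$facility[out$n == 0])
  out
}

#' Facility attendance lower bound
#'
#' Per top facility, the number of predicted-positive windows compared
#' to the number of actual positives — the count of predicted positives
#' serves as a conservative estimate of forthcoming patient access
#' volume.
#'
#' @param yHat binary prediction matrix.
#' @param y binary truth matrix of the same shape.
#' @param nTop number of individually-tracked facilities (default: all
#'   but the last label).
#' @return data.frame per facility: `predicted`, `actual`, `ratio`
#'   (`NA` when there are no actual positives).
#' @export
attendanceLowerBound <- function(yHat, y, nTop = ncol(y) - 1L) {
  if (!all(dim(y) == dim(yHat))) stop("label matrices differ in shape")
  predicted <- colSums(yHat[, seq_len(nTop), drop = FALSE])
  actual <- colSums(y[, seq_len(nTop), drop = FALSE])
  data.frame(facility = seq_len(nTop), predicted = predicted,
             actual = actual,
             ratio = ifelse(actual > 0, predicted / actual, NA_real_))
}

#' Evaluate predictions on a window subset
#'
#' Bundles every evaluation of the pipeline into one report: mean
#' Hamming distance, exact accuracies, per-label and pooled
#' confusion-derived metrics and AUC, first-access accuracy, and the
#' attendance lower bound.
#'
#' @param ws the [WindowSet-class] (raw counts; needed for the
#'   first-access analysis).
#' @param pred a [PredictionScores-class] for the windows in `idx`.
#' @param idx evaluated window indices within `ws` (default: all).
#' @return a [MetricsReport-class].
#' @export
evaluatePredictions <- function(ws, pred, idx = seq_len(nWindows(ws))) {
  y <- ws@y[idx, , drop = FALSE]
  yHat <- pred@yHat
  scores <- pred@c
  per <- perLabelMetrics(y, yHat, scores)
  fa <- firstAccessAccuracy(ws, yHat, idx)
  flags <- c(attr(per, "flags"), attr(fa, "flags"))
  new("MetricsReport",
      meanHamming = mean(hammingDistance(y, yHat)),
      exactAccuracy = exactAccuracy(y, yHat),
      top10ExactAccuracy = exactAccuracy(y, yHat, ignoreLast = TRUE),
      perLabel = per,
      overall = overallMetrics(y, yHat, scores),
      firstAccess = fa,
      lowerBound = attendanceLowerBound(yHat, y),
      n = length(idx),
      flags = as.character(flags))
}

#' Serialize a metrics report
#'
#' `metricsJSON` writes the full report as JSON; `metricsRow` flattens
#' the headline metrics to a single-row data.frame, convenient for
#' aggregating repeated runs.
#'
#' @param report a [MetricsReport-class].
#' @param path optional output file for the JSON form.
#' @export
metricsJSON <- function(report, path = NULL) {
  x <- list(n = report@n,
            mean_hamming = report@meanHamming,
            exact_accuracy = report@exactAccuracy,
            top10_exact_accuracy = report@top10ExactAccuracy,
            overall = as.list(report@overall),
            per_label = report@perLabel,
            first_access = report@firstAccess,
            lower_bound = report@lowerBound,
            flags = report@flags)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname metricsJSON
#' @export
metricsRow <- function(report) {
  data.frame(n = report@n, meanHamming = report@meanHamming,
             exactAccuracy = report@exactAccuracy,
             top10ExactAccuracy = report@top10ExactAccuracy,
             t(report@overall),
             meanFirstAccess = mean(report@firstAccess$accuracy,
                                    na.rm = TRUE),
             lowerBoundRatio = sum(report@lowerBound$predicted) /
               max(1, sum(report@lowerBound$actual)))
}
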