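# Confusion-matrix metrics and cross-validation planning.

#' One-vs-rest confusion counts
#'
#' @param yTrue,yPred integer/factor label vectors of equal length, values
#'   in `1..nClasses` (or 0-based, see `zeroBased`).
#' @param nClasses number of classes.
#' @param zeroBased set `TRUE` when labels run `0..nClasses-1`.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(yTrue, yPred, nClasses, zeroBased = FALSE) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  yTrue <- as.integer(yTrue) + if (zeroBased) 1L else 0L
  yPred <- as.integer(yPred) + if (zeroBased) 1L else 0L
  if (any(yTrue < 1L | yTrue > nClasses | yPred < 1L | yPred > nClasses))
    stop("labels out of range 1..nClasses", call. = FALSE)
  n <- length(yTrue)
  counts <- t(vapply(seq_len(nClasses), function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    c(TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn)
  }, integer(4)))
  rownames(counts) <- paste0("class", seq_len(nClasses))
  new("ConfusionCounts", counts = counts, nSamples = as.integer(n))
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Per class (one-vs-rest): accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` and the harmonic-mean F1 `2PR/(P+R)`.  Zero
#' denominators yield 0 with a warning, never `NaN`.  Macro averages are the
#' unweighted class means; micro averages pool the counts.  The overall
#' `accuracy` slot is the pooled-count accuracy, which equals the fraction
#' of exact label matches.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricsReport-class].
#' @export
classificationMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  cc <- counts@counts
  per <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
    tp <- cc[i, "TP"]; fp <- cc[i, "FP"]; fn <- cc[i, "FN"]; tn <- cc[i, "TN"]
    acc <- (tp + tn) / counts@nSamples
    prec <- safeRatio(tp, tp + fp, "precision")
    rec <- safeRatio(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  }))
  rownames(per) <- rownames(cc)
  macro <- c(accuracy = mean(per$accuracy), precision = mean(per$precision),
             recall = mean(per$recall), f1 = mean(per$f1))
  tp <- sum(cc[, "TP"]); fp <- sum(cc[, "FP"]); fn <- sum(cc[, "FN"])
  mprec <- safeRatio(tp, tp + fp, "micro precision")
  mrec <- safeRatio(tp, tp + fn, "micro recall")
  micro <- c(precision = mprec, recall = mrec,
             f1 = if (mprec + mrec == 0) 0 else
               2 * mprec * mrec / (mprec + mrec))
  overall <- tp / counts@nSamples  # pooled TP = exact matches
  new("MetricsReport", perClass = per, macro = macro, micro = micro,
      accuracy = overall)
}

#' Convenience: metrics straight from label vectors
#'
#' @inheritParams confusionCounts
#' @return a [MetricsReport-class].
#' @export
evaluatePredictions <- function(yTrue, yPred, nClasses,
                                zeroBased = FALSE) {
  classificationMetrics(confusionCounts(yTrue, yPred, nClasses, zeroBased))
}

#' Plan a k-fold cross-validation split
#'
#' Record mode shuffles records and deals them into `k` folds whose sizes
#' differ by at most one.  Subject mode partitions subjects, so all records
#' of a subject share a fold - the split that prevents slice leakage between
#' training and testing in multi-slice imaging data.
#'
#' @param recordIds vector identifying the records (its length defines n).
#' @param subjectIds subject/patient ID per record; required for subject
#'   mode.
#' @param k number of folds (default 10).
#' @param mode "record" or "subject".
#' @param seed RNG seed for the shuffle.
#' @return a [CVPlan-class].
#' @export
crossvalSplit <- function(recordIds, subjectIds = NULL, k = 10L,
                          mode = c("record", "subject"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(recordIds)
  k <- as.integer(k)
  if (mode == "record") {
    if (k > n) stop("k exceeds the number of records", call. = FALSE)
    fold <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    if (is.null(subjectIds))
      stop("subject mode requires subjectIds", call. = FALSE)
    stopifnot(length(subjectIds) == n)
    subj <- unique(subjectIds)
    if (k > length(subj)) stop("k exceeds the number of subjects",
                               call. = FALSE)
    sfold <- withSeed(seed, sample(rep_len(seq_len(k), length(subj))))
    fold <- sfold[match(subjectIds, subj)]
  }
  folds <- lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
  new("CVPlan", folds = folds, k = k, mode = mode, seed = as.integer(seed))
}
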