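# Binary wrapper around the hybrid optimizer: continuous agent positions are
# squashed through a sigmoid transfer function into feature masks, scored by
# a fast 1-nearest-neighbour surrogate under stratified cross-validation.

#' Binarize a continuous position into a selection mask
#'
#' Feature `d` is selected iff `sigmoid(x[d]) > 0.5`, i.e. `x[d] > 0`.  If no
#' coordinate is positive, the dimension with the largest transfer value is
#' forced on so the mask is never empty.
#'
#' @param position finite numeric vector.
#' @return logical vector of the same length, at least one `TRUE`.
#' @export
binarizePosition <- function(position) {
  assertFinite(position, "position")
  mask <- position > 0
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# exact 1-nearest-neighbour labels via a BLAS distance computation; ties
# resolve to the earliest training row
nn1Predict <- function(Xtr, Xte, ytr) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
  ytr[max.col(-d2, "first")]
}

# stratified fold assignment, deterministic in `seed`
stratifiedFolds <- function(labels, k, seed) {
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Wrapper fitness of a feature mask
#'
#' `omega * err + (1 - omega) * count / D`, where `err` is the
#' misclassification rate of a 1-nearest-neighbour surrogate under seeded
#' stratified 3-fold cross-validation restricted to the selected columns.
#' Lower is better; the size penalty breaks ties toward smaller masks.
#'
#' @param mask logical feature mask (at least one `TRUE`).
#' @param features numeric matrix, rows = samples.
#' @param labels class labels, one per row; at least two classes.
#' @param omega weight of the error term (default 0.99).
#' @param seed seed for the fold assignment.
#' @param k number of CV folds (default 3).
#' @return scalar fitness, lower is better.
#' @export
featureFitness <- function(mask, features, labels, omega = 0.99, seed = 1L,
                           k = 3L) {
  stopifnot(is.logical(mask), length(mask) == ncol(features),
            nrow(features) == length(labels))
  if (!any(mask)) stop("mask must select at least one feature", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("labels must contain at least two classes", call. = FALSE)
  X <- features[, mask, drop = FALSE]
  fold <- stratifiedFolds(labels, k, seed)
  errs <- 0L
  for (f in seq_len(k)) {
    te <- fold == f
    pred <- nn1Predict(X[!te, , drop = FALSE], X[te, , drop = FALSE],
                       as.integer(labels)[!te])
    errs <- errs + sum(pred != as.integer(labels)[te])
  }
  err <- errs / length(labels)
  omega * err + (1 - omega) * sum(mask) / length(mask)
}

#' Feature selection with the hybrid wave optimizer
#'
#' Runs [hybOptimize()] over continuous positions in `[-4, 4]^D` with
#' `featureFitness(binarizePosition(x), ...)` as the objective and returns
#' the best mask found together with the best-fitness trace.  Fully
#' reproducible from the seed in `cfg`.
#'
#' @param features numeric matrix, rows = samples, columns = features
#'   (D >= 2).
#' @param labels class labels, one per row.
#' @param cfg a [HybWaveConfig-class].
#' @param omega error weight of the wrapper fitness.
#' @return a [SelectionResult-class].
#' @export
selectFeatures <- function(features, labels, cfg = hybWaveConfig(),
                           omega = 0.99) {
  D <- ncol(features)
  if (D < 2L) stop("need at least two feature columns", call. = FALSE)
  obj <- function(x)
    featureFitness(binarizePosition(x), features, labels, omega = omega,
                   seed = cfg@seed)
  res <- hybOptimize(obj, lb = rep(-4, D), ub = rep(4, D), cfg = cfg)
  new("SelectionResult", mask = binarizePosition(res@bestPosition),
      fitness = res@bestFitness, trace = res@trace, config = cfg)
}
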