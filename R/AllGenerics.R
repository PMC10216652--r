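#' Detail coefficients of a wavelet pyramid
#' @param x a [WaveletPyramid-class].
#' @param level optional level to extract; all levels when missing.
#' @return list of detail bands, or a single band.
#' @export
setGeneric("detailCoefs", function(x, level) standardGeneric("detailCoefs"))

#' @rdname detailCoefs
#' @export
setMethod("detailCoefs", "WaveletPyramid", function(x, level) {
  if (missing(level)) x@detail else x@detail[[level]]
})

#' Approximation band of a wavelet pyramid
#' @param x a [WaveletPyramid-class].
#' @return the coarsest approximation array.
#' @export
setGeneric("approxCoefs", function(x) standardGeneric("approxCoefs"))

#' @rdname approxCoefs
#' @export
setMethod("approxCoefs", "WaveletPyramid", function(x) x@approx)

#' Number of decomposition levels
#' @param x a [WaveletPyramid-class].
#' @return integer level count.
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname nLevels
#' @export
setMethod("nLevels", "WaveletPyramid", function(x) x@levels)

#' Selected feature indices
#' @param x a [SelectionResult-class].
#' @return integer vector of selected column indices.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) which(x@mask))

#' Best-fitness trace of an optimization run
#' @param x a [HybWaveResult-class] or [SelectionResult-class].
#' @return numeric vector, best-ever fitness per iteration.
#' @export
setGeneric("fitnessTrace", function(x) standardGeneric("fitnessTrace"))

#' @rdname fitnessTrace
#' @export
setMethod("fitnessTrace", "HybWaveResult", function(x) x@trace)

#' @rdname fitnessTrace
#' @export
setMethod("fitnessTrace", "SelectionResult", function(x) x@trace)

#' Per-epoch training log
#' @param x a [UNetModel-class] or [DenseNetModel-class].
#' @return data.frame with one row per epoch.
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @rdname trainLog
#' @export
setMethod("trainLog", "UNetModel", function(x) x@log)

#' @rdname trainLog
#' @export
setMethod("trainLog", "DenseNetModel", function(x) x@log)

#' Cross-validation folds
#' @param x a [CVPlan-class].
#' @return list of `list(train=, test=)` index pairs.
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))

#' @rdname cvFolds
#' @export
setMethod("cvFolds", "CVPlan", function(x) x@folds)

#' Per-class metric table
#' @param x a [MetricsReport-class].
#' @return data.frame of per-class metrics.
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname perClassMetrics
#' @export
setMethod("perClassMetrics", "MetricsReport", function(x) x@perClass)

#' Macro-averaged metrics
#' @param x a [MetricsReport-class].
#' @return named numeric vector (precision, recall, f1, accuracy).
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname macroMetrics
#' @export
setMethod("macroMetrics", "MetricsReport", function(x) x@macro)

setMethod("show", "WaveletPyramid", function(object) {
  cat("WaveletPyramid:", object@levels, "level(s),",
      paste(object@dims, collapse = "x"), "input, wavelet",
      object@wavelet, "\n")
})

setMethod("show", "HybWaveResult", function(object) {
  cat("HybWaveResult: best fitness", format(object@bestFitness),
      "in", length(object@bestPosition), "dimensions,",
      object@evaluations, "evaluations\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", sum(object@mask), "of", length(object@mask),
      "features selected; fitness", format(object@fitness), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport: accuracy", round(object@accuracy, 4), "\n")
  print(round(object@perClass, 4))
  cat("macro:", paste(names(object@macro),
                      round(object@macro, 4), collapse = ", "), "\n")
})

setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", object@k, "folds,", object@mode, "mode, seed",
      object@seed, "\n")
})

setMethod("show", "UNetModel", function(object) {
  cat("UNetModel: depth", object@config@depth, "baseFilters",
      object@config@baseFilters, "input", object@inputDim, "x",
      object@inputDim, "-", nrow(object@log), "epochs trained\n")
})

setMethod("show", "DenseNetModel", function(object) {
  cat("DenseNetModel: preset", object@config@preset, "k",
      object@config@growthRate, "blocks",
      paste(object@config@blockSizes, collapse = "-"), "input",
      object@config@inputSize, "\n")
})
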