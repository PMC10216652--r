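#' WaveletPyramid: undecimated wavelet decomposition
#'
#' Container for a stationary (undecimated, periodic) wavelet decomposition.
#' Every detail band has the same size as the input signal/image; for 2-D
#' inputs each level holds the three orientation bands `LH`, `HL`, `HH`.
#'
#' @slot detail list of per-level coefficient arrays, finest scale first; for
#'   2-D inputs each element is itself a list of the three orientation bands.
#' @slot approx coarsest approximation band (same shape as the input).
#' @slot levels integer number of decomposition levels M.
#' @slot wavelet name of the mother wavelet ("haar", "db2", "db4").
#' @slot dims dimensions of the decomposed signal (length 1 or 2).
#' @export
setClass("WaveletPyramid",
  representation(detail = "list", approx = "ANY", levels = "integer",
                 wavelet = "character", dims = "integer"),
  validity = function(object) {
    if (object@levels < 1L) return("levels must be >= 1")
    if (length(object@detail) != object@levels)
      return("detail must hold one entry per level")
    TRUE
  })

#' CorrelationMap: hierarchical inter-scale correlation
#'
#' Per-position product of detail coefficients across `nScales` adjacent
#' scales starting at `baseScale`; large where genuine edges align across
#' scales, small where noise dominates.
#'
#' @slot values array (or per-orientation list of arrays) with the same shape
#'   as one detail band.
#' @slot baseScale first scale entering the product (m).
#' @slot nScales number of scales multiplied (l).
#' @export
setClass("CorrelationMap",
  representation(values = "ANY", baseScale = "integer", nScales = "integer"),
  validity = function(object) {
    if (object@nScales < 2L) return("nScales must be >= 2")
    if (object@baseScale < 1L) return("baseScale must be >= 1")
    TRUE
  })

#' DenoiseParams: spatially selective wavelet denoiser settings
#'
#' @slot levels number of undecimated decomposition levels (default 3).
#' @slot wavelet mother wavelet name; default "db2", a smooth 4-tap
#'   orthogonal wavelet.
#' @slot corrScales number of adjacent scales multiplied into the
#'   correlation map (default 2).
#' @slot maxPasses contour-extraction pass budget per scale (default 3).
#' @slot residualPowerFraction stop once the residual detail power at a scale
#'   falls below this fraction of its original power (default 0.1).
#' @export
setClass("DenoiseParams",
  representation(levels = "integer", wavelet = "character",
                 corrScales = "integer", maxPasses = "integer",
                 residualPowerFraction = "numeric"),
  prototype(levels = 3L, wavelet = "db2", corrScales = 2L, maxPasses = 3L,
            residualPowerFraction = 0.1),
  validity = function(object) {
    if (object@corrScales < 2L) return("corrScales must be >= 2")
    if (object@levels < object@corrScales)
      return("levels must be >= corrScales")
    if (object@residualPowerFraction <= 0 || object@residualPowerFraction >= 1)
      return("residualPowerFraction must lie in (0, 1)")
    if (object@maxPasses < 1L) return("maxPasses must be >= 1")
    TRUE
  })

#' Construct denoiser parameters
#'
#' @param levels,wavelet,corrScales,maxPasses,residualPowerFraction see the
#'   slots of [DenoiseParams-class].
#' @return a `DenoiseParams` object.
#' @export
denoiseParams <- function(levels = 3L, wavelet = "db2", corrScales = 2L,
                          maxPasses = 3L, residualPowerFraction = 0.1) {
  new("DenoiseParams", levels = as.integer(levels), wavelet = wavelet,
      corrScales = as.integer(corrScales), maxPasses = as.integer(maxPasses),
      residualPowerFraction = residualPowerFraction)
}

#' ContourDecomposition: contour / residual split of a pyramid
#'
#' Result of the iterative contour-extraction procedure: coefficients judged
#' to sit on image outlines are moved into `kept`; everything else stays in
#' `residual`.  Per scale and band, `kept` and `residual` partition the input
#' detail energy exactly.
#'
#' @slot mask logical array (or per-orientation list), TRUE at positions
#'   marked as contour locations.
#' @slot kept [WaveletPyramid-class] holding the contour coefficients.
#' @slot residual [WaveletPyramid-class] holding the non-contour coefficients
#'   and the approximation band.
#' @slot passes number of extraction passes actually run at the base scale.
#' @export
setClass("ContourDecomposition",
  representation(mask = "ANY", kept = "WaveletPyramid",
                 residual = "WaveletPyramid", passes = "integer"))

#' HybWaveConfig: hybrid water-wave / whale optimizer settings
#'
#' @slot popSize number of search agents (waves/whales), >= 2.
#' @slot iterations number of optimization iterations.
#' @slot alpha wavelength reduction base (default 1.0026).
#' @slot epsilon small constant guarding the wavelength exponent
#'   (default 1e-12).
#' @slot hMax initial/reset wave height, the stagnation budget (default 6).
#' @slot bSpiral logarithmic-spiral shape constant b (default 1).
#' @slot pThreshold probability threshold between the spiral and the
#'   encircle/explore branches (default 0.5).
#' @slot pHybrid probability that an agent takes a water-wave propagation
#'   step instead of a whale step (default 0.5).
#' @slot seed RNG seed making a run fully reproducible.
#' @export
setClass("HybWaveConfig",
  representation(popSize = "integer", iterations = "integer",
                 alpha = "numeric", epsilon = "numeric", hMax = "integer",
                 bSpiral = "numeric", pThreshold = "numeric",
                 pHybrid = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@popSize < 2L) return("popSize must be >= 2")
    if (object@iterations < 1L) return("iterations must be >= 1")
    if (object@pHybrid < 0 || object@pHybrid > 1)
      return("pHybrid must lie in [0, 1]")
    if (object@alpha <= 1) return("alpha must exceed 1")
    TRUE
  })

#' Construct optimizer settings
#'
#' @param popSize,iterations,alpha,epsilon,hMax,bSpiral,pThreshold,pHybrid,seed
#'   see the slots of [HybWaveConfig-class].
#' @return a `HybWaveConfig` object.
#' @export
hybWaveConfig <- function(popSize = 20L, iterations = 100L, alpha = 1.0026,
                          epsilon = 1e-12, hMax = 6L, bSpiral = 1,
                          pThreshold = 0.5, pHybrid = 0.5, seed = 1L) {
  new("HybWaveConfig", popSize = as.integer(popSize),
      iterations = as.integer(iterations), alpha = alpha, epsilon = epsilon,
      hMax = as.integer(hMax), bSpiral = bSpiral, pThreshold = pThreshold,
      pHybrid = pHybrid, seed = as.integer(seed))
}

#' HybWaveResult: outcome of a hybrid optimization run
#'
#' @slot bestPosition best-ever position found.
#' @slot bestFitness its (minimized) objective value.
#' @slot trace best-ever fitness after each iteration; non-increasing.
#' @slot evaluations total objective evaluations spent.
#' @slot config the [HybWaveConfig-class] used.
#' @export
setClass("HybWaveResult",
  representation(bestPosition = "numeric", bestFitness = "numeric",
                 trace = "numeric", evaluations = "integer",
                 config = "HybWaveConfig"))

#' SelectionResult: binary feature-selection outcome
#'
#' @slot mask logical vector over feature columns; never empty.
#' @slot fitness wrapper fitness of the returned mask (lower is better).
#' @slot trace best-ever fitness per iteration.
#' @slot config the optimizer configuration used.
#' @export
setClass("SelectionResult",
  representation(mask = "logical", fitness = "numeric", trace = "numeric",
                 config = "HybWaveConfig"),
  validity = function(object) {
    if (!any(object@mask)) return("selection mask must never be empty")
    TRUE
  })

#' UNetConfig: shallow U-Net autoencoder training configuration
#'
#' Defaults follow the training recipe used for the feature extractor: batch
#' size 64, up to 100 epochs with early-stopping patience 15, MSE loss under
#' the Adam optimizer with MAE as the tracked metric.
#'
#' @slot depth number of down/up-sampling levels (default 2, the shallow
#'   variant).
#' @slot baseFilters channels of the first encoder stage (default 16).
#' @slot batchSize minibatch size (default 64).
#' @slot epochs maximum epochs (default 100).
#' @slot patience early-stopping patience in epochs (default 15).
#' @slot optimizer optimizer name ("adam").
#' @slot loss loss name ("mse").
#' @slot metric tracked metric name ("mae").
#' @slot valFraction fraction of images held out for early stopping
#'   (default 0.1).
#' @slot lr Adam learning rate.
#' @slot seed RNG seed.
#' @export
setClass("UNetConfig",
  representation(depth = "integer", baseFilters = "integer",
                 batchSize = "integer", epochs = "integer",
                 patience = "integer", optimizer = "character",
                 loss = "character", metric = "character",
                 valFraction = "numeric", lr = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@patience > object@epochs)
      return("patience must not exceed epochs")
    TRUE
  })

#' Construct a U-Net training configuration
#' @param depth,baseFilters,batchSize,epochs,patience,optimizer,loss,metric,valFraction,lr,seed
#'   see the slots of [UNetConfig-class].
#' @return a `UNetConfig` object.
#' @export
unetConfig <- function(depth = 2L, baseFilters = 16L, batchSize = 64L,
                       epochs = 100L, patience = 15L, optimizer = "adam",
                       loss = "mse", metric = "mae", valFraction = 0.1,
                       lr = 1e-3, seed = 1L) {
  new("UNetConfig", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), patience = as.integer(patience),
      optimizer = optimizer, loss = loss, metric = metric,
      valFraction = valFraction, lr = lr, seed = as.integer(seed))
}

#' UNetModel: trained shallow U-Net autoencoder
#'
#' @slot params environment holding the trained parameter tensors.
#' @slot config the [UNetConfig-class] used for training.
#' @slot log per-epoch data.frame of training/validation loss and metric.
#' @slot inputDim spatial input size the model was trained on.
#' @export
setClass("UNetModel",
  representation(params = "environment", config = "UNetConfig",
                 log = "data.frame", inputDim = "integer"))

#' DenseNetConfig: dense convolutional classifier configuration
#'
#' @slot growthRate channels k appended by every dense layer (default 12).
#' @slot blockSizes layer counts of the four dense blocks.
#' @slot inputSize spatial input size (default 224).
#' @slot nClasses number of output classes (default 3).
#' @slot nChannels input channels; 4 builds four parallel stems fused by two
#'   combination blocks.
#' @slot preset "text" (7x7 stride-2 stem, 3x3 stride-2 pool, 1x1+3x3
#'   bottlenecks) or "table1" (8x8 stem, 4x4 pool, per-block kernel sizes as
#'   tabulated).
#' @slot lr Adam learning rate for training.
#' @slot batchSize minibatch size.
#' @slot seed RNG seed.
#' @export
setClass("DenseNetConfig",
  representation(growthRate = "integer", blockSizes = "integer",
                 inputSize = "integer", nClasses = "integer",
                 nChannels = "integer", preset = "character", lr = "numeric",
                 batchSize = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@blockSizes) != 4L || any(object@blockSizes < 1L))
      return("blockSizes must be four integers >= 1")
    if (object@nClasses < 2L) return("nClasses must be >= 2")
    if (!object@preset %in% c("text", "table1"))
      return("preset must be 'text' or 'table1'")
    TRUE
  })

#' Construct a DenseNet configuration
#' @param growthRate,blockSizes,inputSize,nClasses,nChannels,preset,lr,batchSize,seed
#'   see the slots of [DenseNetConfig-class].
#' @return a `DenseNetConfig` object.
#' @export
denseNetConfig <- function(growthRate = 12L, blockSizes = c(6L, 12L, 24L, 16L),
                           inputSize = 224L, nClasses = 3L, nChannels = 1L,
                           preset = "text", lr = 1e-3, batchSize = 16L,
                           seed = 1L) {
  new("DenseNetConfig", growthRate = as.integer(growthRate),
      blockSizes = as.integer(blockSizes), inputSize = as.integer(inputSize),
      nClasses = as.integer(nClasses), nChannels = as.integer(nChannels),
      preset = preset, lr = lr, batchSize = as.integer(batchSize),
      seed = as.integer(seed))
}

#' DenseNetModel: built (optionally trained) dense convolutional classifier
#'
#' @slot params environment holding parameter tensors and batch-norm state.
#' @slot config the [DenseNetConfig-class].
#' @slot log per-epoch training log (empty until trained).
#' @slot shapes data.frame of layer names and spatial/channel arithmetic,
#'   filled in at construction and asserted against the forward pass.
#' @export
setClass("DenseNetModel",
  representation(params = "environment", config = "DenseNetConfig",
                 log = "data.frame", shapes = "data.frame"))

#' ConfusionCounts: one-vs-rest confusion counts per class
#'
#' @slot counts integer matrix, one row per class, columns TP/FP/FN/TN.
#' @slot nSamples total number of scored samples.
#' @export
setClass("ConfusionCounts",
  representation(counts = "matrix", nSamples = "integer"),
  validity = function(object) {
    if (!identical(colnames(object@counts), c("TP", "FP", "FN", "TN")))
      return("counts must have columns TP, FP, FN, TN")
    if (any(rowSums(object@counts) != object@nSamples))
      return("TP+FP+FN+TN must equal nSamples for every class")
    TRUE
  })

#' MetricsReport: per-class and aggregate classification metrics
#'
#' @slot perClass data.frame with accuracy, precision, recall and F1 per
#'   class (one-vs-rest).
#' @slot macro named numeric vector of macro-averaged metrics.
#' @slot micro named numeric vector of micro-averaged (pooled) metrics.
#' @slot accuracy overall multi-class accuracy (fraction of exact matches).
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", macro = "numeric",
                 micro = "numeric", accuracy = "numeric"))

#' CVPlan: cross-validation fold plan
#'
#' @slot folds list of `list(train=, test=)` integer index pairs.
#' @slot k number of folds.
#' @slot mode "record" (fold over records) or "subject" (all records of a
#'   subject share a fold, preventing slice leakage).
#' @slot seed RNG seed used for the shuffle.
#' @export
setClass("CVPlan",
  representation(folds = "list", k = "integer", mode = "character",
                 seed = "integer"))
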