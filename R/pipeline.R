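# End-to-end orchestration: phantoms (or a provided image set) -> denoise ->
# autoencoder features -> hybrid feature selection -> classifier -> metrics.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    phantoms = list(n = 120L, size = 32L, classes = 3L, classEffect = 2,
                    noiseSd = 0.1),
    denoise = list(enabled = TRUE, levels = 3L, wavelet = "db2"),
    features = list(depth = 2L, baseFilters = 8L, batchSize = 16L,
                    epochs = 3L, patience = 3L),
    select = list(popSize = 12L, iterations = 30L, omega = 0.99),
    classify = list(epochs = 30L, lr = 1e-3, batchSize = 16L),
    split = list(testFraction = 0.25)
  )
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      mergeConfig(defaults[[nm]], user[[nm]])
    else user[[nm]]
  }
  defaults
}

stageLog <- function(stage, seed, t0) {
  message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs",
                  format(Sys.time(), "%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full pipeline on synthetic phantoms
#'
#' Executes every stage in sequence at desk scale: phantom generation,
#' wavelet denoising, shallow U-Net autoencoder training and bottleneck
#' feature extraction, hybrid wave feature selection, classifier training on
#' the selected features, and held-out evaluation with a subject-aware
#' split (no subject appears in both halves).  `config` overrides any
#' subset of the defaults (see the methods vignette); structured progress
#' lines report stage, seed and elapsed time.
#'
#' @param config nested list of stage settings, merged over the defaults.
#' @return list with `selection` ([SelectionResult-class]), `model` (the
#'   trained classifier), `metrics` ([MetricsReport-class] on the held-out
#'   records), `featureDim`, and the merged `config`.
#' @export
runPipeline <- function(config = list()) {
  cfg <- mergeConfig(pipelineDefaults(), config)
  seed <- as.integer(cfg$seed)
  t0 <- Sys.time()

  ph <- makePhantomImages(nImages = cfg$phantoms$n,
                          imageSize = cfg$phantoms$size,
                          nClasses = cfg$phantoms$classes,
                          classEffect = cfg$phantoms$classEffect,
                          noiseSd = cfg$phantoms$noiseSd, seed = seed)
  stageLog("phantoms", seed, t0)

  imgs <- ph$images
  if (isTRUE(cfg$denoise$enabled)) {
    dp <- denoiseParams(levels = cfg$denoise$levels,
                        wavelet = cfg$denoise$wavelet)
    imgs <- lapply(imgs, function(im) zeroCenter(waveDenoise(im, dp)))
    stageLog("denoise", seed, t0)
  } else {
    imgs <- lapply(imgs, zeroCenter)
  }

  uc <- unetConfig(depth = cfg$features$depth,
                   baseFilters = cfg$features$baseFilters,
                   batchSize = cfg$features$batchSize,
                   epochs = cfg$features$epochs,
                   patience = cfg$features$patience, seed = seed)
  model <- trainAutoencoder(imgs, uc)
  feats <- extractFeatureMatrix(model, imgs)
  stageLog("features", seed, t0)

  # subject-aware split: held-out subjects, not just held-out slices
  subj <- unique(ph$subjectIds)
  nTest <- max(1L, round(cfg$split$testFraction * length(subj)))
  testSubj <- withSeed(seed, sample(subj, nTest))
  te <- ph$subjectIds %in% testSubj
  sel <- selectFeatures(feats[!te, , drop = FALSE], ph$labels[!te],
                        hybWaveConfig(popSize = cfg$select$popSize,
                                      iterations = cfg$select$iterations,
                                      seed = seed),
                        omega = cfg$select$omega)
  stageLog("select", seed, t0)

  dcfg <- denseNetConfig(nClasses = cfg$phantoms$classes,
                         lr = cfg$classify$lr,
                         batchSize = cfg$classify$batchSize, seed = seed)
  clf <- trainClassifier(feats[!te, sel@mask, drop = FALSE],
                         ph$labels[!te], dcfg,
                         epochs = cfg$classify$epochs)
  stageLog("classify", seed, t0)

  p <- predictProb(clf, feats[te, sel@mask, drop = FALSE])
  metrics <- evaluatePredictions(ph$labels[te], max.col(p, "first"),
                                 cfg$phantoms$classes)
  stageLog("evaluate", seed, t0)

  list(selection = sel, model = clf, metrics = metrics,
       featureDim = ncol(feats), config = cfg)
}
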