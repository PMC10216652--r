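# Dense convolutional classification head.  Two presets: "text" follows the
# internally consistent narrative architecture (7x7 stride-2 stem, 3x3
# stride-2 max-pool, 1x1+3x3 bottleneck layers, so 224 -> 112 -> 56), while
# "table1" reproduces the tabulated kernel sizes (8x8 stem, 4x4 pool,
# per-block 5/1/5/7 convolutions, per-transition 2/4/6/8 convolutions).

#' Prediction: class probabilities and the arg-max label
#'
#' @slot probabilities numeric vector, non-negative, sums to 1.
#' @slot label integer arg-max class (ties broken toward the lowest index).
#' @export
setClass("Prediction",
  representation(probabilities = "numeric", label = "integer"),
  validity = function(object) {
    if (abs(sum(object@probabilities) - 1) > 1e-6)
      return("probabilities must sum to 1")
    if (any(object@probabilities < 0))
      return("probabilities must be non-negative")
    TRUE
  })

setMethod("show", "Prediction", function(object) {
  cat("Prediction: class", object@label, "(",
      paste(round(object@probabilities, 4), collapse = ", "), ")\n")
})

#' Channel count after a dense block
#'
#' Dense connectivity concatenates every earlier feature map, so a block of
#' `nLayers` layers with growth rate `k` maps `c0` input channels to
#' `c0 + nLayers * k`.
#'
#' @param c0 input channels.
#' @param nLayers layers in the block.
#' @param k growth rate.
#' @return integer output channel count.
#' @export
denseBlockChannels <- function(c0, nLayers, k) {
  stopifnot(c0 >= 0, nLayers >= 0, k >= 0)
  as.integer(c0 + nLayers * k)
}

densenetHyper <- function(cfg) {
  if (cfg@preset == "text") {
    list(stemK = 7L, stemStride = 2L, stemPad = 3L,
         poolK = 3L, poolStride = 2L, poolPad = 1L,
         blockK = rep(3L, 4L), transK = rep(1L, 4L))
  } else {
    list(stemK = 8L, stemStride = 2L, stemPad = 3L,
         poolK = 4L, poolStride = 2L, poolPad = 1L,
         blockK = c(5L, 1L, 5L, 7L), transK = c(2L, 4L, 6L, 8L))
  }
}

# "same"-size padding for a stride-1 conv; even kernels over-pad by one and
# the forward pass crops back
samePad <- function(k) as.integer(k %/% 2L)

#' Build a dense convolutional classifier
#'
#' Constructs the parameter set and the layer-by-layer size arithmetic for
#' the configured preset.  The spatial size after every stage follows
#' `floor((n + 2p - f)/s) + 1` and is recorded in the model's shape table,
#' which the forward pass asserts against.  With `nChannels = 4` four
#' parallel stems are built and fused by two 1x1 combination blocks before
#' the dense blocks.
#'
#' @param cfg a [DenseNetConfig-class].
#' @return an untrained [DenseNetModel-class].
#' @export
buildDenseNet <- function(cfg = denseNetConfig()) {
  stopifnot(is(cfg, "DenseNetConfig"))
  set.seed(cfg@seed)
  hp <- densenetHyper(cfg)
  k <- cfg@growthRate
  stemC <- 2L * k
  shapes <- data.frame(stage = "input", spatial = cfg@inputSize,
                       channels = cfg@nChannels)
  s1 <- convOutSize(cfg@inputSize, hp$stemK, hp$stemStride, hp$stemPad)
  s2 <- convOutSize(s1, hp$poolK, hp$poolStride, hp$poolPad)
  if (s2 < 8L)
    stop("configuration error: input size ", cfg@inputSize,
         " leaves only ", s2, " pixels after layer 'stem+pool'; ",
         "the three transition poolings need at least 8", call. = FALSE)
  nStem <- if (cfg@nChannels == 4L) 4L else 1L
  stems <- lapply(seq_len(nStem), function(i)
    list(conv = initConvParam(hp$stemK, hp$stemK, 1L, stemC),
         bn = initBNParam(stemC)))
  shapes <- rbind(shapes,
                  data.frame(stage = "stem", spatial = s1, channels = stemC),
                  data.frame(stage = "pool", spatial = s2, channels = stemC))
  combs <- NULL
  c0 <- stemC
  if (nStem == 4L) {
    combs <- list(
      c1 = initConvParam(1L, 1L, 2L * stemC, stemC),
      c2 = initConvParam(1L, 1L, 2L * stemC, stemC))
    c0 <- 2L * stemC
    shapes <- rbind(shapes, data.frame(stage = "fusion", spatial = s2,
                                       channels = c0))
  }
  blocks <- list(); trans <- list()
  sp <- s2
  for (b in 1:4) {
    nl <- cfg@blockSizes[b]
    layers <- lapply(seq_len(nl), function(li) {
      cin <- denseBlockChannels(c0, li - 1L, k)
      list(bn1 = initBNParam(cin),
           conv1 = initConvParam(1L, 1L, cin, 4L * k),
           bn2 = initBNParam(4L * k),
           conv2 = initConvParam(hp$blockK[b], hp$blockK[b], 4L * k, k))
    })
    blocks[[b]] <- layers
    c0 <- denseBlockChannels(c0, nl, k)
    shapes <- rbind(shapes, data.frame(stage = sprintf("block%d", b),
                                       spatial = sp, channels = c0))
    if (b < 4L) {
      cT <- c0 %/% 2L
      trans[[b]] <- list(bn = initBNParam(c0),
                         conv = initConvParam(hp$transK[b], hp$transK[b],
                                              c0, cT))
      c0 <- cT
      sp <- sp %/% 2L
      if (sp < 1L)
        stop("configuration error: spatial size collapses at layer ",
             sprintf("'transition%d'", b), call. = FALSE)
      shapes <- rbind(shapes, data.frame(stage = sprintf("transition%d", b),
                                         spatial = sp, channels = c0))
    }
  }
  head <- list(bn = initBNParam(c0),
               fc1 = initDenseParam(c0, 64L),
               fc2 = initDenseParam(64L, 32L),
               fc3 = initDenseParam(32L, cfg@nClasses))
  shapes <- rbind(shapes, data.frame(stage = "head", spatial = 1L,
                                     channels = cfg@nClasses))
  env <- new.env(parent = emptyenv())
  env$pp <- list(stems = stems, combs = combs, blocks = blocks,
                 trans = trans, head = head, hp = hp)
  new("DenseNetModel", params = env, config = cfg, log = data.frame(),
      shapes = shapes)
}

# forward pass; x: (H, W, nChannels, N) array.  `ablate = c(block, layer)`
# zeroes that layer's appended feature map, demonstrating that later layers
# really consume it (dense connectivity).
densenetForward <- function(model, x, training = FALSE, ablate = NULL) {
  pp <- model@params$pp
  cfg <- model@config
  hp <- pp$hp
  expect <- model@shapes
  stemOf <- function(xin, st) {
    h <- opConv2d(xin, st$conv$W, st$conv$b, stride = hp$stemStride,
                  pad = hp$stemPad)
    h <- opRelu(opBatchNorm(h, st$bn$gamma, st$bn$beta, training))
    opMaxPool(h, hp$poolK, hp$poolStride, hp$poolPad)
  }
  if (length(pp$stems) == 4L) {
    parts <- lapply(1:4, function(i)
      stemOf(nnNode(nnVal(x)[, , i, , drop = FALSE]), pp$stems[[i]]))
    f1 <- opConv2d(opConcat(parts[1:2]), pp$combs$c1$W, pp$combs$c1$b)
    f2 <- opConv2d(opConcat(parts[3:4]), pp$combs$c2$W, pp$combs$c2$b)
    h <- opConcat(list(f1, f2))
  } else {
    h <- stemOf(x, pp$stems[[1]])
  }
  sPool <- expect$spatial[expect$stage == "pool"]
  stopifnot(dim(nnVal(h))[1] == sPool)
  for (b in 1:4) {
    feats <- list(h)
    for (li in seq_along(pp$blocks[[b]])) {
      ly <- pp$blocks[[b]][[li]]
      hin <- if (length(feats) == 1L) feats[[1]] else opConcat(feats)
      z <- opRelu(opBatchNorm(hin, ly$bn1$gamma, ly$bn1$beta, training))
      z <- opConv2d(z, ly$conv1$W, ly$conv1$b)
      z <- opRelu(opBatchNorm(z, ly$bn2$gamma, ly$bn2$beta, training))
      kb <- hp$blockK[b]
      z <- opConv2d(z, ly$conv2$W, ly$conv2$b, pad = samePad(kb))
      d0 <- dim(nnVal(hin))
      z <- opCropTo(z, d0[1], d0[2])
      if (!is.null(ablate) && ablate[1] == b && ablate[2] == li)
        z <- nnNode(nnVal(z) * 0)
      feats[[length(feats) + 1L]] <- z
    }
    h <- opConcat(feats)
    sb <- expect$spatial[expect$stage == sprintf("block%d", b)]
    cb <- expect$channels[expect$stage == sprintf("block%d", b)]
    stopifnot(dim(nnVal(h))[1] == sb, dim(nnVal(h))[3] == cb)
    if (b < 4L) {
      tr <- pp$trans[[b]]
      h <- opRelu(opBatchNorm(h, tr$bn$gamma, tr$bn$beta, training))
      kt <- hp$transK[b]
      d0 <- dim(nnVal(h))
      h <- opConv2d(h, tr$conv$W, tr$conv$b, pad = samePad(kt))
      h <- opCropTo(h, d0[1], d0[2])
      h <- opAvgPool2(h)
    }
  }
  h <- opRelu(opBatchNorm(h, pp$head$bn$gamma, pp$head$bn$beta, training))
  h <- opGlobalAvgPool(h)
  h <- opRelu(opDense(h, pp$head$fc1$W, pp$head$fc1$b))
  h <- opRelu(opDense(h, pp$head$fc2$W, pp$head$fc2$b))
  opDense(h, pp$head$fc3$W, pp$head$fc3$b)   # logits (N, nClasses)
}

# dense-only variant for pre-extracted (selected) feature vectors
mlpInit <- function(D, nClasses) {
  list(fc1 = initDenseParam(D, 64L), fc2 = initDenseParam(64L, 32L),
       fc3 = initDenseParam(32L, nClasses))
}

mlpForward <- function(pp, x) {
  h <- opRelu(opDense(x, pp$fc1$W, pp$fc1$b))
  h <- opRelu(opDense(h, pp$fc2$W, pp$fc2$b))
  opDense(h, pp$fc3$W, pp$fc3$b)
}

#' Train the dense classifier
#'
#' Cross-entropy training with Adam.  `inputs` may be a list of image
#' matrices (the convolutional network of [buildDenseNet()] is used) or a
#' numeric matrix of feature vectors - for example HybWWoA-selected
#' features - in which case only the three dense head layers are trained and
#' the convolutional stem is skipped.
#'
#' @param inputs list of image matrices, or a samples x features matrix.
#' @param labels integer class labels in `1..nClasses` (factors allowed).
#' @param cfg a [DenseNetConfig-class].
#' @param epochs training epochs.
#' @return a trained [DenseNetModel-class] with a per-epoch log of loss and
#'   training accuracy.
#' @export
trainClassifier <- function(inputs, labels, cfg = denseNetConfig(),
                            epochs = 20L) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L)
    stop("need at least two classes present", call. = FALSE)
  stopifnot(max(labels) <= cfg@nClasses)
  featureKind <- is.matrix(inputs)
  n <- if (featureKind) nrow(inputs) else length(inputs)
  stopifnot(n == length(labels))
  if (featureKind) {
    set.seed(cfg@seed)
    env <- new.env(parent = emptyenv())
    env$pp <- list(mlp = mlpInit(ncol(inputs), cfg@nClasses))
    model <- new("DenseNetModel", params = env, config = cfg,
                 log = data.frame(),
                 shapes = data.frame(stage = "features", spatial = 1L,
                                     channels = ncol(inputs)))
  } else {
    model <- buildDenseNet(cfg)
  }
  pp <- model@params$pp
  params <- collectParams(pp)
  log <- data.frame()
  step <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
    eLoss <- 0; correct <- 0L
    for (bt in batches) {
      if (featureKind) {
        xb <- nnNode(inputs[bt, , drop = FALSE])
        logits <- mlpForward(pp$mlp, xb)
      } else {
        xb <- nnNode(stackImages(inputs[bt]))
        logits <- densenetForward(model, xb, training = TRUE)
      }
      loss <- opSoftmaxCELoss(logits, labels[bt])
      if (!is.finite(loss$value)) stop("non-finite training loss")
      lossVal <- loss$value
      pred <- max.col(nnVal(logits), "first")
      nnZeroGrads(params)
      nnBackward(loss)
      step <- step + 1L
      adamStep(params, cfg@lr, step)
      eLoss <- eLoss + lossVal * length(bt)
      correct <- correct + sum(pred == labels[bt])
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = eLoss / n,
                                 accuracy = correct / n))
  }
  model@log <- log
  model
}

#' Predict class probabilities for a batch
#'
#' @param model a trained [DenseNetModel-class].
#' @param inputs list of image matrices or a feature matrix, matching the
#'   kind the model was trained on.
#' @return matrix of probabilities, one row per input.
#' @export
predictProb <- function(model, inputs) {
  pp <- model@params$pp
  if (!is.null(pp$mlp)) {
    stopifnot(is.matrix(inputs))
    logits <- nnVal(mlpForward(pp$mlp, nnNode(inputs)))
  } else {
    stopifnot(is.list(inputs))
    d <- dim(inputs[[1]])
    if (d[1] != model@config@inputSize)
      stop("input size does not match the model", call. = FALSE)
    logits <- nnVal(densenetForward(model, nnNode(stackImages(inputs)),
                                    training = FALSE))
  }
  softmaxRows(logits)
}

#' Predict a single input
#'
#' @param model a trained [DenseNetModel-class].
#' @param input one image matrix (or a single feature row vector).
#' @return a [Prediction-class]; the label is the arg-max with ties broken
#'   toward the lowest class index.
#' @export
predictClass <- function(model, input) {
  p <- if (is.matrix(input) && !is.null(model@params$pp$mlp))
    predictProb(model, input)
  else if (is.matrix(input)) predictProb(model, list(input))
  else predictProb(model, matrix(input, 1L))
  new("Prediction", probabilities = as.vector(p[1L, ]),
      label = which.max(p[1L, ]))
}
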