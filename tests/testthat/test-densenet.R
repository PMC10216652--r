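test_that("dense-block channel growth is c0 + nLayers * k", {
  expect_equal(denseBlockChannels(64, 0, 12), 64L)
  expect_equal(denseBlockChannels(64, 4, 12), 112L)
  # introspection: the built model's shape table obeys the same arithmetic
  cfg <- denseNetConfig(growthRate = 8, blockSizes = c(2, 3, 1, 2),
                        inputSize = 64, nClasses = 2, seed = 1)
  m <- buildDenseNet(cfg)
  sh <- m@shapes
  c0 <- sh$channels[sh$stage == "pool"]
  for (b in 1:4) {
    expect_equal(sh$channels[sh$stage == sprintf("block%d", b)],
                 denseBlockChannels(c0, cfg@blockSizes[b], 8))
    c0 <- denseBlockChannels(c0, cfg@blockSizes[b], 8) %/% 2L
  }
})

test_that("preset 'text' halves 224 to 112 then 56 through stem and pool", {
  m <- buildDenseNet(denseNetConfig(growthRate = 4, inputSize = 224,
                                    preset = "text", seed = 1))
  sh <- m@shapes
  expect_equal(sh$spatial[sh$stage == "stem"], 112)
  expect_equal(sh$spatial[sh$stage == "pool"], 56)
  # spatial sizes follow floor((n + 2p - f)/s) + 1 at every layer
  cos <- TumorWaveNet:::convOutSize
  expect_equal(cos(224L, 7L, 2L, 3L), 112L)
  expect_equal(cos(112L, 3L, 2L, 1L), 56L)
})

test_that("forward pass emits normalized class probabilities", {
  cfg <- denseNetConfig(growthRate = 6, blockSizes = c(1, 1, 1, 1),
                        inputSize = 32, nClasses = 3, seed = 2)
  m <- buildDenseNet(cfg)
  set.seed(3)
  imgs <- lapply(1:4, function(i) matrix(rnorm(32 * 32), 32))
  p <- predictProb(m, imgs)
  expect_equal(dim(p), c(4L, 3L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  # deterministic prediction, arg-max label
  pr1 <- predictClass(m, imgs[[1]])
  pr2 <- predictClass(m, imgs[[1]])
  expect_identical(pr1@probabilities, pr2@probabilities)
  expect_equal(pr1@label, which.max(pr1@probabilities))
  expect_error(predictProb(m, lapply(1:2, function(i) matrix(0, 16, 16))),
               "does not match")
})

test_that("the 'table1' preset builds and runs with tabulated kernels", {
  cfg <- denseNetConfig(growthRate = 4, blockSizes = c(1, 1, 1, 1),
                        inputSize = 64, nClasses = 2, preset = "table1",
                        seed = 4)
  m <- buildDenseNet(cfg)
  set.seed(5)
  p <- predictProb(m, list(matrix(rnorm(64 * 64), 64)))
  expect_true(abs(sum(p) - 1) < 1e-6)
  # table-1 stem: 8x8 kernel stride 2 still halves the input
  expect_equal(m@shapes$spatial[m@shapes$stage == "stem"], 32)
})

test_that("dense connectivity is real: ablating an early layer changes output", {
  cfg <- denseNetConfig(growthRate = 6, blockSizes = c(2, 1, 1, 1),
                        inputSize = 32, nClasses = 2, seed = 6)
  m <- buildDenseNet(cfg)
  set.seed(7)
  x <- TumorWaveNet:::stackImages(list(matrix(rnorm(32 * 32), 32)))
  full <- TumorWaveNet:::nnVal(
    TumorWaveNet:::densenetForward(m, TumorWaveNet:::nnNode(x)))
  ablated <- TumorWaveNet:::nnVal(
    TumorWaveNet:::densenetForward(m, TumorWaveNet:::nnNode(x),
                                   ablate = c(1, 1)))
  expect_gt(max(abs(full - ablated)), 1e-8)
})

test_that("four-channel fusion builds parallel stems and combination blocks", {
  cfg <- denseNetConfig(growthRate = 4, blockSizes = c(1, 1, 1, 1),
                        inputSize = 32, nClasses = 3, nChannels = 4,
                        seed = 8)
  m <- buildDenseNet(cfg)
  expect_equal(m@shapes$channels[m@shapes$stage == "fusion"], 16)  # 2*stemC
  set.seed(9)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4, 1))
  logits <- TumorWaveNet:::nnVal(
    TumorWaveNet:::densenetForward(m, TumorWaveNet:::nnNode(x)))
  p <- TumorWaveNet:::softmaxRows(logits)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("tiny-config training fits easy phantoms and stays finite", {
  ph <- makePhantomImages(nImages = 60, imageSize = 32, nClasses = 2,
                          seed = 10)
  cfg <- denseNetConfig(growthRate = 6, blockSizes = c(1, 1, 1, 1),
                        inputSize = 32, nClasses = 2, batchSize = 12,
                        seed = 1)
  m <- trainClassifier(ph$images, ph$labels, cfg, epochs = 4)
  lg <- trainLog(m)
  expect_true(all(is.finite(lg$loss)))
  expect_lt(lg$loss[4], lg$loss[1])
  expect_gt(lg$accuracy[4], 0.6)
  expect_error(trainClassifier(ph$images, rep(1, 60), cfg), "two classes")
})

test_that("feature-vector inputs train the dense head only", {
  d <- makeFeatureDataset(nSamples = 120, nFeatures = 10, nInformative = 3,
                          effect = 2.5, seed = 11)
  cfg <- denseNetConfig(nClasses = 2, batchSize = 20, seed = 2)
  m <- trainClassifier(d$features, d$labels, cfg, epochs = 30)
  expect_gt(tail(trainLog(m)$accuracy, 1), 0.8)
  p <- predictProb(m, d$features)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  pr <- predictClass(m, d$features[1, ])
  expect_s4_class(pr, "Prediction")
})

test_that("impossible size arithmetic is rejected with the layer named", {
  expect_error(buildDenseNet(denseNetConfig(inputSize = 16)),
               "stem\\+pool")
})
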