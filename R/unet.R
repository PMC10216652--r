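# Shallow U-Net autoencoder feature extraction, plus the pixel-wise
# soft-max, border weight map and weighted cross-entropy operators that make
# up the segmentation-style objective.

#' WeightMap: pixel weighting for class balancing and border emphasis
#'
#' @slot values non-negative weight grid `w(x)`.
#' @slot wc per-class balancing weights (inverse class frequency, normalized
#'   to pixel-mean 1).
#' @slot w0 border emphasis amplitude.
#' @slot sigma border emphasis length scale (pixels).
#' @export
setClass("WeightMap",
  representation(values = "matrix", wc = "numeric", w0 = "numeric",
                 sigma = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) return("weights must be non-negative")
    TRUE
  })

#' Pixel-wise soft-max over activation channels
#'
#' Converts K per-channel activation grids into per-channel probability
#' grids: at every pixel `p_k = exp(a_k) / sum_j exp(a_j)`, computed with
#' max-subtraction for numerical stability.  Probabilities at each pixel are
#' non-negative and sum to one; adding a constant to all channels leaves
#' them unchanged.
#'
#' @param activations array `(H, W, K)` with `K >= 2`, or a list of K
#'   same-size matrices.
#' @return array `(H, W, K)` of probabilities.
#' @export
softmaxMap <- function(activations) {
  if (is.list(activations))
    activations <- array(unlist(activations),
                         c(dim(activations[[1]]), length(activations)))
  stopifnot(length(dim(activations)) == 3L)
  K <- dim(activations)[3]
  if (K < 2L) stop("need at least two channels", call. = FALSE)
  assertFinite(activations, "activations")
  mx <- apply(activations, c(1, 2), max)
  e <- exp(activations - as.vector(mx))
  s <- apply(e, c(1, 2), sum)
  e / as.vector(s)
}

# distance from every pixel to the border pixels of each connected
# foreground component; returns an (nPix x nComp) matrix
componentBorderDistances <- function(labelMask) {
  fg <- labelMask > 0
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  nComp <- max(comp)
  if (nComp == 0L) return(NULL)
  H <- nrow(labelMask); W <- ncol(labelMask)
  rows <- row(labelMask); cols <- col(labelMask)
  pad <- function(m) {
    out <- matrix(0, H + 2L, W + 2L); out[2:(H + 1), 2:(W + 1)] <- m; out
  }
  d <- matrix(Inf, H * W, nComp)
  for (ci in seq_len(nComp)) {
    inC <- comp == ci
    p <- pad(inC)
    interior <- p[1:H, 2:(W + 1)] & p[3:(H + 2), 2:(W + 1)] &
      p[2:(H + 1), 1:W] & p[2:(H + 1), 3:(W + 2)]
    border <- inC & !interior
    br <- rows[border]; bc <- cols[border]
    d[, ci] <- sqrt(do.call(pmin, c(lapply(seq_along(br), function(i)
      (as.vector(rows) - br[i])^2 + (as.vector(cols) - bc[i])^2),
      list(Inf))))
  }
  d
}

#' Border-weighted class-balancing weight map
#'
#' `w(x) = wc(x) + w0 * exp(-(d1(x) + d2(x))^2 / (2 sigma^2))` where `wc` is
#' the inverse-class-frequency weight (normalized to pixel-mean 1) and `d1`,
#' `d2` are the Euclidean distances to the borders of the nearest and
#' second-nearest foreground components.  With a single component `d2 = d1`;
#' with no foreground the map reduces to `wc` alone.
#'
#' @param labelMask integer matrix of pixel labels (0 = background).
#' @param w0 border emphasis amplitude (default 10).
#' @param sigma border length scale in pixels (default 5).
#' @return a [WeightMap-class].
#' @export
classWeightMap <- function(labelMask, w0 = 10, sigma = 5) {
  stopifnot(is.matrix(labelMask))
  vals <- as.vector(labelMask)
  freq <- table(vals) / length(vals)
  inv <- 1 / as.numeric(freq)
  names(inv) <- names(freq)
  wcxRaw <- inv[as.character(vals)]
  wcx <- wcxRaw / mean(wcxRaw)                # pixel-mean 1
  wc <- inv / mean(wcxRaw)                    # per-class, same scale
  d <- componentBorderDistances(labelMask)
  w <- if (is.null(d)) {
    wcx
  } else {
    d1 <- apply(d, 1, min)
    d2 <- if (ncol(d) >= 2L) apply(d, 1, function(z) sort(z)[2]) else d1
    wcx + w0 * exp(-(d1 + d2)^2 / (2 * sigma^2))
  }
  new("WeightMap", values = matrix(w, nrow(labelMask)), wc = wc,
      w0 = w0, sigma = sigma)
}

#' Weighted cross-entropy over a probability map
#'
#' `E = -sum_x w(x) log p_{l(x)}(x)`: the negative log-likelihood of the
#' ground-truth labels under the soft-max map, weighted per pixel.
#' Probabilities are clipped at `1e-12` before the logarithm; E is zero for
#' a perfect prediction and non-negative otherwise.
#'
#' @param p probability array `(H, W, K)` from [softmaxMap()].
#' @param labels integer matrix of ground-truth classes in `0..K-1`.
#' @param weights a [WeightMap-class], a numeric matrix, or a scalar.
#' @return scalar penalty E >= 0.
#' @export
weightedCrossEntropy <- function(p, labels, weights = 1) {
  stopifnot(length(dim(p)) == 3L)
  H <- dim(p)[1]; W <- dim(p)[2]; K <- dim(p)[3]
  if (!is.matrix(labels) || nrow(labels) != H || ncol(labels) != W)
    stop("labels shape does not match the probability map", call. = FALSE)
  if (any(labels < 0L | labels >= K))
    stop("labels must lie in 0..K-1", call. = FALSE)
  w <- if (is(weights, "WeightMap")) weights@values else weights
  if (is.matrix(w) && !all(dim(w) == c(H, W)))
    stop("weight map shape mismatch", call. = FALSE)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  pTrue <- pmax(p[idx], 1e-12)
  -sum(as.vector(if (is.matrix(w)) w else matrix(w, H, W)) * log(pTrue))
}

#' Segmentation loss head
#'
#' Composes the three operators: soft-max over the activation channels, the
#' border weight map of the ground truth, and the weighted cross-entropy.
#' Usable as a training objective whenever label masks exist.
#'
#' @param activations array `(H, W, K)` of raw per-channel activations.
#' @param labels integer matrix of classes in `0..K-1`.
#' @param w0,sigma weight-map parameters, see [classWeightMap()].
#' @return scalar penalty.
#' @export
segmentationLoss <- function(activations, labels, w0 = 10, sigma = 5) {
  weightedCrossEntropy(softmaxMap(activations), labels,
                       classWeightMap(labels, w0, sigma))
}

#' Random elastic-style augmentation
#'
#' Applies one randomly composed geometric transform - horizontal flip,
#' width/height shift, shear and zoom - by inverse-mapped bilinear sampling
#' with zero fill outside the support.  A supplied label mask receives the
#' identical geometric transform (nearest-neighbour sampling).  Parameter
#' magnitudes of zero reproduce the input exactly.
#'
#' @param image numeric matrix.
#' @param seed RNG seed for the parameter draw.
#' @param maxShift maximum shift as a fraction of the image side
#'   (default 0.1).
#' @param maxShear maximum shear coefficient (default 0.1).
#' @param zoomRange multiplicative zoom range (default `c(0.9, 1.1)`).
#' @param flipProb probability of a horizontal flip (default 0.5).
#' @param mask optional integer matrix transformed identically.
#' @return augmented matrix, or `list(image=, mask=)` when a mask is given.
#' @export
elasticAugment <- function(image, seed = 1L, maxShift = 0.1, maxShear = 0.1,
                           zoomRange = c(0.9, 1.1), flipProb = 0.5,
                           mask = NULL) {
  stopifnot(is.matrix(image))
  pars <- withSeed(seed, list(
    flip = runif(1) < flipProb,
    dr = runif(1, -maxShift, maxShift) * nrow(image),
    dc = runif(1, -maxShift, maxShift) * ncol(image),
    shear = runif(1, -maxShear, maxShear),
    zoom = runif(1, zoomRange[1], zoomRange[2])))
  out <- affineSample(image, pars, bilinear = TRUE)
  if (is.null(mask)) return(out)
  list(image = out, mask = affineSample(mask, pars, bilinear = FALSE))
}

# forward transform about the image centre: flip -> shear -> zoom -> shift.
# Sampling is inverse-mapped: for each output pixel the source location is
# found by inverting the affine map analytically.
affineSample <- function(image, pars, bilinear = TRUE) {
  H <- nrow(image); W <- ncol(image)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  # forward matrix in centred (row, col) coordinates
  M <- matrix(c(pars$zoom, 0, pars$zoom * pars$shear, pars$zoom), 2, 2)
  if (pars$flip) M[, 2] <- -M[, 2]
  Minv <- solve(M)
  og <- expand.grid(r = seq_len(H), c = seq_len(W))
  rc <- rbind(og$r - cr - pars$dr, og$c - cc - pars$dc)
  src <- Minv %*% rc
  sr <- src[1, ] + cr; sc <- src[2, ] + cc
  if (bilinear) {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(r, c) {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- numeric(length(r))
      v[ok] <- image[cbind(r[ok], c[ok])]
      v
    }
    v <- gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  } else {
    r0 <- round(sr); c0 <- round(sc)
    ok <- r0 >= 1 & r0 <= H & c0 >= 1 & c0 <= W
    v <- numeric(length(sr))
    v[ok] <- image[cbind(r0[ok], c0[ok])]
  }
  matrix(v, H, W)
}

#' Early-stopping rule
#'
#' Given a sequence of per-epoch validation losses, returns the epoch at
#' which training stops: the first epoch after which `patience` consecutive
#' epochs have passed without improving on the best loss so far (or the last
#' epoch when that never happens).
#'
#' @param losses numeric vector of validation losses, one per epoch.
#' @param patience number of epochs without improvement tolerated.
#' @return integer stopping epoch.
#' @export
earlyStopEpoch <- function(losses, patience) {
  best <- Inf; since <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) { best <- losses[e]; since <- 0L }
    else {
      since <- since + 1L
      if (since >= patience) return(e)
    }
  }
  length(losses)
}

# build the parameter set for a shallow U-Net autoencoder
unetInitParams <- function(depth, baseFilters, inChannels = 1L) {
  enc <- list()
  cin <- inChannels
  for (lev in seq_len(depth)) {
    f <- baseFilters * 2L^(lev - 1L)
    enc[[lev]] <- list(c1 = initConvParam(3L, 3L, cin, f),
                       c2 = initConvParam(3L, 3L, f, f))
    cin <- f
  }
  fb <- baseFilters * 2L^depth
  bott <- list(c1 = initConvParam(3L, 3L, cin, fb),
               c2 = initConvParam(3L, 3L, fb, fb))
  dec <- list()
  cup <- fb
  for (lev in rev(seq_len(depth))) {
    f <- baseFilters * 2L^(lev - 1L)
    dec[[lev]] <- list(c1 = initConvParam(3L, 3L, cup + f, f),
                       c2 = initConvParam(3L, 3L, f, f))
    cup <- f
  }
  out <- initConvParam(1L, 1L, cup, inChannels)
  list(enc = enc, bott = bott, dec = dec, out = out, depth = depth,
       baseFilters = baseFilters)
}

unetForward <- function(pp, x) {
  skips <- list()
  h <- x
  for (lev in seq_len(pp$depth)) {
    h <- opRelu(opConv2d(h, pp$enc[[lev]]$c1$W, pp$enc[[lev]]$c1$b, pad = 1L))
    h <- opRelu(opConv2d(h, pp$enc[[lev]]$c2$W, pp$enc[[lev]]$c2$b, pad = 1L))
    skips[[lev]] <- h
    h <- opMaxPool(h, 2L)
  }
  h <- opRelu(opConv2d(h, pp$bott$c1$W, pp$bott$c1$b, pad = 1L))
  h <- opRelu(opConv2d(h, pp$bott$c2$W, pp$bott$c2$b, pad = 1L))
  bottleneck <- h
  for (lev in rev(seq_len(pp$depth))) {
    h <- opUpsample2(h)
    h <- opConcat(list(h, skips[[lev]]))
    h <- opRelu(opConv2d(h, pp$dec[[lev]]$c1$W, pp$dec[[lev]]$c1$b, pad = 1L))
    h <- opRelu(opConv2d(h, pp$dec[[lev]]$c2$W, pp$dec[[lev]]$c2$b, pad = 1L))
  }
  h <- opConv2d(h, pp$out$W, pp$out$b)
  list(out = h, bottleneck = bottleneck)
}

#' Train the shallow U-Net autoencoder
#'
#' Trains the encoder-decoder to reconstruct its input under MSE with Adam,
#' tracking MAE, exactly as configured by [unetConfig()]: a seeded
#' validation split drives early stopping with the configured patience.  The
#' per-epoch log records training loss/MAE and validation loss/MAE.
#'
#' @param images list of same-size numeric matrices (at least `batchSize`).
#' @param config a [UNetConfig-class].
#' @return a [UNetModel-class]; inspect the log with [trainLog()].
#' @export
trainAutoencoder <- function(images, config = unetConfig()) {
  stopifnot(is(config, "UNetConfig"))
  n <- length(images)
  if (n < config@batchSize)
    stop("need at least batchSize images", call. = FALSE)
  d <- dim(images[[1]])
  if (d[1] != d[2]) stop("images must be square", call. = FALSE)
  if (d[1] %% 2L^config@depth != 0L)
    stop("image side must be divisible by 2^depth", call. = FALSE)
  set.seed(config@seed)
  pp <- unetInitParams(config@depth, config@baseFilters)
  params <- collectParams(pp)
  nVal <- max(1L, round(config@valFraction * n))
  ord <- sample.int(n)
  valIdx <- ord[seq_len(nVal)]
  trIdx <- ord[-seq_len(nVal)]
  xVal <- stackImages(images[valIdx])
  log <- data.frame()
  step <- 0L
  bestVal <- Inf
  sinceBest <- 0L
  for (epoch in seq_len(config@epochs)) {
    idx <- sample(trIdx)
    batches <- split(idx, ceiling(seq_along(idx) / config@batchSize))
    eLoss <- eMae <- 0
    for (bt in batches) {
      xb <- stackImages(images[bt])
      fw <- unetForward(pp, nnNode(xb))
      loss <- opMSELoss(fw$out, xb)
      lossVal <- loss$value
      maeVal <- mean(abs(nnVal(fw$out) - xb))
      nnZeroGrads(params)
      nnBackward(loss)
      step <- step + 1L
      adamStep(params, config@lr, step)
      eLoss <- eLoss + lossVal * length(bt)
      eMae <- eMae + maeVal * length(bt)
    }
    fwV <- unetForward(pp, xVal)
    vl <- mean((nnVal(fwV$out) - xVal)^2)
    vm <- mean(abs(nnVal(fwV$out) - xVal))
    log <- rbind(log, data.frame(
      epoch = epoch, loss = eLoss / length(trIdx), mae = eMae / length(trIdx),
      valLoss = vl, valMae = vm))
    if (vl < bestVal) { bestVal <- vl; sinceBest <- 0L }
    else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config@patience) break
    }
  }
  env <- new.env(parent = emptyenv())
  env$pp <- pp
  new("UNetModel", params = env, config = config, log = log,
      inputDim = as.integer(d[1]))
}

#' Extract the bottleneck feature vector of an image
#'
#' Runs the trained autoencoder's encoder and returns the flattened
#' bottleneck activations: a deterministic feature vector of dimension
#' `baseFilters * 2^depth * (inputDim / 2^depth)^2`.
#'
#' @param model a [UNetModel-class].
#' @param image numeric matrix matching the model's input size.
#' @return numeric feature vector.
#' @export
extractFeatures <- function(model, image) {
  stopifnot(is(model, "UNetModel"), is.matrix(image))
  if (nrow(image) != model@inputDim || ncol(image) != model@inputDim)
    stop("image size does not match the trained model", call. = FALSE)
  fw <- unetForward(model@params$pp, stackImages(list(image)))
  as.vector(nnVal(fw$bottleneck))
}

#' Extract features for a list of images
#'
#' @param model a [UNetModel-class].
#' @param images list of matrices.
#' @return numeric matrix, one row per image.
#' @export
extractFeatureMatrix <- function(model, images) {
  t(vapply(images, function(im) extractFeatures(model, im),
           numeric(featureDim(model))))
}

#' Feature dimension of a trained autoencoder
#' @param model a [UNetModel-class].
#' @return integer bottleneck dimension after flattening.
#' @export
featureDim <- function(model) {
  cfg <- model@config
  as.integer(cfg@baseFilters * 2L^cfg@depth *
               (model@inputDim / 2L^cfg@depth)^2)
}
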