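# Seeded synthetic generators: elliptical tumor phantoms, labeled feature
# matrices with a known informative subset, and noisy piecewise-constant
# signals.  Pure functions of their arguments - the same spec regenerates
# identical data - so every pipeline stage is testable without downloads.

#' Generate elliptical tumor phantom images
#'
#' Each image is a dark background carrying one bright elliptical "tumor"
#' whose size, eccentricity and mean intensity depend on the class label,
#' plus i.i.d. Gaussian noise.  Class `c` has mean intensity
#' `0.5 + (c - 1) * classEffect * noiseSd`, so `classEffect` is the class
#' separation in noise-SD units.  Images are grouped four per synthetic
#' subject (consecutive), mimicking multi-slice patients, to exercise
#' subject-wise cross-validation.
#'
#' @param nImages number of images.
#' @param imageSize square image side in pixels.
#' @param nClasses number of classes (>= 2); labels cycle so the class
#'   histogram is balanced within one image.
#' @param classEffect mean-intensity separation between adjacent classes in
#'   units of `noiseSd` (default 2).
#' @param noiseSd Gaussian noise standard deviation (default 0.1, on a
#'   [0, 1]-ish intensity scale).
#' @param seed RNG seed.
#' @return list with `images` (list of matrices), `labels` (integer vector,
#'   1-based) and `subjectIds` (character vector).
#' @export
makePhantomImages <- function(nImages = 200L, imageSize = 64L, nClasses = 3L,
                              classEffect = 2, noiseSd = 0.1, seed = 1L) {
  stopifnot(nClasses >= 2L, classEffect > 0)
  labels <- rep_len(seq_len(nClasses), nImages)
  subjectIds <- sprintf("S%03d", (seq_len(nImages) - 1L) %/% 4L + 1L)
  ctr <- (imageSize + 1) / 2
  xy <- expand.grid(row = seq_len(imageSize), col = seq_len(imageSize))
  images <- withSeed(seed, lapply(seq_len(nImages), function(i) {
    cl <- labels[i]
    # class-dependent geometry: radius and eccentricity grow with the class
    rA <- imageSize * (0.12 + 0.05 * (cl - 1)) * runif(1, 0.9, 1.1)
    rB <- rA * (1 - 0.15 * (cl - 1)) * runif(1, 0.9, 1.1)
    cx <- ctr + runif(1, -2, 2)
    cy <- ctr + runif(1, -2, 2)
    inside <- ((xy$row - cx) / rA)^2 + ((xy$col - cy) / rB)^2 <= 1
    img <- matrix(0.1, imageSize, imageSize)
    img[matrix(inside, imageSize)] <- 0.5 + (cl - 1) * classEffect * noiseSd
    img + matrix(rnorm(imageSize^2, sd = noiseSd), imageSize)
  }))
  list(images = images, labels = labels, subjectIds = subjectIds)
}

#' Generate a labeled feature matrix with known informative columns
#'
#' Informative columns carry class-dependent means separated by `effect`
#' standard deviations; the remaining columns are pure standard-normal
#' noise.  The returned `trueMask` marks the informative columns, giving
#' selection experiments an exact ground truth.
#'
#' @param nSamples number of rows.
#' @param nFeatures total feature count.
#' @param nInformative number of informative columns (< `nFeatures`).
#' @param effect class-mean separation in SD units (default 1.5).
#' @param nClasses number of classes (default 2).
#' @param seed RNG seed.
#' @return list with `features` (matrix), `labels` (integer vector) and
#'   `trueMask` (logical vector).
#' @export
makeFeatureDataset <- function(nSamples = 200L, nFeatures = 50L,
                               nInformative = 5L, effect = 1.5,
                               nClasses = 2L, seed = 1L) {
  stopifnot(nInformative < nFeatures, nClasses >= 2L)
  labels <- rep_len(seq_len(nClasses), nSamples)
  withSeed(seed, {
    X <- matrix(rnorm(nSamples * nFeatures), nSamples, nFeatures)
    informative <- sample.int(nFeatures, nInformative)
    for (j in informative)
      X[, j] <- X[, j] + (labels - 1) * effect
    trueMask <- logical(nFeatures)
    trueMask[informative] <- TRUE
    colnames(X) <- sprintf("f%02d", seq_len(nFeatures))
    list(features = X, labels = labels, trueMask = trueMask)
  })
}

#' Generate a noisy piecewise-constant signal
#'
#' The clean signal is piecewise constant with a step of the given amplitude
#' starting at each edge position; Gaussian noise of SD `noiseSd` is added.
#'
#' @param length signal length.
#' @param edgePositions 1-based indices where a new segment begins.
#' @param amplitudes step heights added at each edge (same length as
#'   `edgePositions`).
#' @param noiseSd Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with `clean` and `noisy` numeric vectors.
#' @export
makeNoisySignal <- function(length = 1024L, edgePositions = c(300L, 700L),
                            amplitudes = c(1, -0.6), noiseSd = 0.1,
                            seed = 1L) {
  stopifnot(length(edgePositions) == length(amplitudes),
            all(edgePositions >= 1L), all(edgePositions <= length))
  clean <- numeric(length)
  for (i in seq_along(edgePositions))
    clean[edgePositions[i]:length] <- clean[edgePositions[i]:length] +
      amplitudes[i]
  noisy <- withSeed(seed, clean + rnorm(length, sd = noiseSd))
  list(clean = clean, noisy = noisy)
}
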