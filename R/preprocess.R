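# Image standardization: fixed-grid padding/scaling, zero-centering and the
# horizontal shift augmentation applied before feature extraction.

#' Pad and rescale an image onto a fixed square grid
#'
#' Images smaller than the target grid are zero-padded and centered; images
#' with a side exceeding the target are first rescaled (bilinear, aspect
#' ratio preserved) so the longer side equals the target, then zero-padded to
#' square.  The default grid is 900 x 900.
#'
#' @param image numeric matrix (single-channel intensities, row-major,
#'   origin top-left).
#' @param target side length of the square output grid (default 900).
#' @return a `target` x `target` numeric matrix.
#' @export
padAndResize <- function(image, target = 900L) {
  if (!is.matrix(image) || any(dim(image) == 0L))
    stop("image must be a non-empty matrix", call. = FALSE)
  assertFinite(image, "image")
  target <- as.integer(target)
  h <- nrow(image); w <- ncol(image)
  if (max(h, w) > target) {
    sc <- target / max(h, w)
    nh <- max(1L, as.integer(round(h * sc)))
    nw <- max(1L, as.integer(round(w * sc)))
    image <- EBImage::imageData(EBImage::resize(
      EBImage::Image(image), w = nh, h = nw))
    h <- nrow(image); w <- ncol(image)
  }
  out <- matrix(0, target, target)
  r0 <- (target - h) %/% 2L
  c0 <- (target - w) %/% 2L
  out[r0 + seq_len(h), c0 + seq_len(w)] <- image
  out
}

#' Zero-center an image
#'
#' Subtracts the per-image mean so the result has mean exactly zero, as
#' required by the U-Net feature extractor's input convention.
#'
#' @param image numeric matrix with finite values.
#' @return matrix of the same shape with mean 0.
#' @export
zeroCenter <- function(image) {
  stopifnot(is.matrix(image))
  assertFinite(image, "image")
  image - mean(image)
}

#' Left-right shift augmentation
#'
#' Produces `count` copies of the image, each shifted horizontally by an
#' integer drawn uniformly from `[-maxShift, maxShift]`; vacated columns are
#' zero-filled.  Fully reproducible given `seed`.
#'
#' @param image numeric matrix.
#' @param maxShift maximum absolute shift in pixels; must be smaller than
#'   the image width.
#' @param count number of augmented copies.
#' @param seed RNG seed.
#' @return list of `count` matrices.
#' @export
shiftAugment <- function(image, maxShift, count, seed = 1L) {
  stopifnot(is.matrix(image))
  if (maxShift >= ncol(image))
    stop("maxShift must be smaller than the image width", call. = FALSE)
  shifts <- withSeed(seed,
    sample.int(2L * maxShift + 1L, count, replace = TRUE) - maxShift - 1L)
  lapply(shifts, function(s) {
    out <- matrix(0, nrow(image), ncol(image))
    if (s >= 0) {
      keep <- seq_len(ncol(image) - s)
      out[, keep + s] <- image[, keep]
    } else {
      keep <- seq_len(ncol(image) + s)
      out[, keep] <- image[, keep - s]
    }
    out
  })
}
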