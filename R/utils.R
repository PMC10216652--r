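#' @import methods
#' @importFrom stats runif rnorm median mad sd quantile
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards.  Keeps helper randomness (fold assignment, fixtures) from
# perturbing user-level simulations.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assertFinite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

#' Peak signal-to-noise ratio
#'
#' PSNR in decibels between a reference signal/image and a distorted one,
#' using the dynamic range of the reference as the peak.
#'
#' @param reference numeric vector or matrix, the clean reference.
#' @param x numeric vector or matrix of the same shape, the signal to score.
#' @param peak peak value; defaults to the dynamic range of `reference`.
#' @return PSNR in dB (`Inf` for an exact match).
#' @export
psnr <- function(reference, x, peak = diff(range(reference))) {
  stopifnot(length(reference) == length(x))
  mse <- mean((as.numeric(reference) - as.numeric(x))^2)
  if (mse == 0) return(Inf)
  if (peak <= 0) peak <- max(abs(reference))
  10 * log10(peak^2 / mse)
}

# squared l2 power of a numeric structure (list-aware)
powerOf <- function(x) {
  if (is.list(x)) sum(vapply(x, powerOf, numeric(1))) else sum(x^2)
}
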