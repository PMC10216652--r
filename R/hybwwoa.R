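# Hybrid water-wave / whale optimizer (HybWWoA).
#
# Each search agent is a water wave (position, wavelength delta, height h)
# that moves either by WWO propagation or by one of the three whale moves
# (encircle / spiral / random-agent exploration).  Height counts successive
# non-improvements; at zero the wave refracts toward the best solution.
# All operator functions draw from R's current RNG stream; hybOptimize()
# seeds it from its config so complete runs are reproducible.

#' Water-wave propagation step
#'
#' Moves a wave by `runif(-1, 1) * delta * L(d)` per dimension; any
#' coordinate leaving its bounds is resampled uniformly inside them.
#'
#' @param position numeric position vector.
#' @param wavelength wavelength delta (> 0 step multiplier; 0 keeps the
#'   position fixed).
#' @param lb,ub numeric bound vectors (recycled to the position length).
#' @return new position vector, within bounds.
#' @export
wavePropagate <- function(position, wavelength, lb, ub) {
  D <- length(position)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  L <- ub - lb
  x <- position + runif(D, -1, 1) * wavelength * L
  out <- x < lb | x > ub
  if (any(out)) x[out] <- lb[out] + runif(sum(out)) * L[out]
  x
}

#' Wavelength update
#'
#' Canonical water-wave wavelength schedule, oriented for minimization:
#' `delta * alpha^(-(f - fmin + eps) / (fmax - fmin + eps))`.  The worst wave
#' (f = fmax) has its wavelength divided by alpha; the best wave keeps it
#' (asymptotically, for eps much smaller than the fitness range).
#'
#' @param wavelength current wavelength.
#' @param f fitness of the wave.
#' @param fmax,fmin population extremes of the fitness (fmax >= fmin).
#' @param alpha reduction base (> 1).
#' @param epsilon small positive guard.
#' @return updated wavelength (> 0).
#' @export
updateWavelength <- function(wavelength, f, fmax, fmin, alpha = 1.0026,
                             epsilon = 1e-12) {
  stopifnot(fmax >= fmin)
  wavelength * alpha^(-(f - fmin + epsilon) / (fmax - fmin + epsilon))
}

#' Refraction toward the best solution
#'
#' Applied when a wave's height reaches zero (stagnation): each coordinate is
#' redrawn from a Gaussian centred midway between the wave and the best
#' position with standard deviation half their distance, the height is reset
#' to `hMax`, and the wavelength is rescaled by the old/new fitness ratio.
#'
#' @param position stagnated position.
#' @param best best-ever position.
#' @param wavelength current wavelength.
#' @param fOld fitness at `position`.
#' @param fNew fitness at the refracted position (supply after evaluating;
#'   when `NULL` only the position is returned).
#' @param lb,ub bounds; the refracted point is clamped inside.
#' @return list with `position` and, when `fNew` is given, `wavelength`.
#' @export
waveRefract <- function(position, best, wavelength, fOld, fNew = NULL,
                        lb = -Inf, ub = Inf) {
  D <- length(position)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  x <- rnorm(D, mean = (best + position) / 2, sd = abs(best - position) / 2)
  x <- pmin(pmax(x, lb), ub)
  out <- list(position = x)
  if (!is.null(fNew))
    out$wavelength <- wavelength * fOld / ifelse(fNew == 0, fOld, fNew)
  out
}

#' Whale coefficient vectors
#'
#' Draws the coefficient pair `A = 2 a r - a`, `C = 2 r'` with independent
#' uniform r, r' in `[0, 1]`; `a` decays linearly from 2 to 0 over the run.
#'
#' @param a current decay value in `[0, 2]`.
#' @param d number of dimensions (independent draws per dimension).
#' @return list with numeric vectors `A` (in `[-a, a]`) and `C` (in
#'   `[0, 2]`).
#' @export
woaCoefficients <- function(a, d = 1L) {
  stopifnot(a >= 0, a <= 2)
  list(A = 2 * a * runif(d) - a, C = 2 * runif(d))
}

#' Deterministic whale move primitives
#'
#' The three position updates of the whale algorithm with their random
#' coefficients passed in explicitly: `woaEncircle` contracts toward the
#' best agent (`X' = X* - A |C X* - X|`), `woaSpiral` takes the
#' logarithmic-spiral path around it
#' (`X' = |X* - X| e^(b l) cos(2 pi l) + X*`), and `woaExplore` searches
#' around a randomly chosen agent (`X' = Xr - A |C Xr - X|`).
#'
#' @param position current agent position.
#' @param best best position so far.
#' @param other a randomly chosen agent's position (exploration).
#' @param A,C coefficient vectors from [woaCoefficients()].
#' @param b spiral shape constant.
#' @param l spiral parameter in `[-1, 1]`.
#' @return new position vector (not yet clamped to bounds).
#' @export
woaEncircle <- function(position, best, A, C) {
  best - A * abs(C * best - position)
}

#' @rdname woaEncircle
#' @export
woaSpiral <- function(position, best, b, l) {
  abs(best - position) * exp(b * l) * cos(2 * pi * l) + best
}

#' @rdname woaEncircle
#' @export
woaExplore <- function(position, other, A, C) {
  other - A * abs(C * other - position)
}

#' One whale move
#'
#' With probability `1 - pThreshold` (p below the threshold): encircle the
#' best agent when `|A| < 1` (`X' = X* - A |C X* - X|`-style contraction), or
#' explore around a random agent otherwise; with the remaining probability
#' take the logarithmic-spiral move around the best agent.  The result is
#' clamped to the bounds.
#'
#' @param position current agent position.
#' @param best best position so far.
#' @param population matrix of all agent positions (rows = agents), used by
#'   the exploration branch.
#' @param a whale decay value in `[0, 2]`.
#' @param cfg a [HybWaveConfig-class] (`bSpiral`, `pThreshold`).
#' @param lb,ub bounds.
#' @return new position vector within bounds.
#' @export
woaMove <- function(position, best, population, a, cfg, lb, ub) {
  D <- length(position)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  p <- runif(1)
  if (p >= cfg@pThreshold) {
    l <- runif(1, -1, 1)
    x <- woaSpiral(position, best, cfg@bSpiral, l)
  } else {
    co <- woaCoefficients(a, D)
    if (all(abs(co$A) < 1)) {
      x <- woaEncircle(position, best, co$A, co$C)
    } else {
      other <- population[sample.int(nrow(population), 1L), ]
      x <- woaExplore(position, other, co$A, co$C)
    }
  }
  pmin(pmax(x, lb), ub)
}

#' Hybrid water-wave / whale optimization
#'
#' Minimizes `objective` over a box.  Per iteration each agent takes a WWO
#' propagation step with probability `pHybrid` (greedy acceptance, height
#' reset on improvement, decrement otherwise) and a whale move with the
#' complementary probability (always accepted, height bookkeeping by
#' improvement); wavelengths follow [updateWavelength()] each iteration, and
#' an agent whose height reaches zero refracts toward the best-ever
#' solution.  The returned trace of best-ever fitness is non-increasing.
#'
#' @param objective function mapping a numeric position vector to a scalar
#'   to be minimized.
#' @param lb,ub bounds (vectors of length `dim`, or scalars with `dim`
#'   supplied).
#' @param cfg a [HybWaveConfig-class].
#' @param dim problem dimension; inferred from `lb` when missing.
#' @return a [HybWaveResult-class].
#' @export
hybOptimize <- function(objective, lb, ub, cfg = hybWaveConfig(),
                        dim = length(lb)) {
  stopifnot(is.function(objective), is(cfg, "HybWaveConfig"))
  D <- as.integer(dim)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  if (any(ub <= lb)) stop("ub must exceed lb elementwise", call. = FALSE)
  set.seed(cfg@seed)
  n <- cfg@popSize
  X <- matrix(runif(n * D, rep(lb, each = n), rep(ub, each = n)), n, D)
  fit <- apply(X, 1, objective)
  evals <- n
  delta <- rep(0.5, n)
  height <- rep(cfg@hMax, n)
  bi <- which.min(fit)
  bestX <- X[bi, ]; bestF <- fit[bi]
  trace <- numeric(cfg@iterations)
  for (t in seq_len(cfg@iterations)) {
    a <- 2 * (1 - (t - 1) / max(1L, cfg@iterations - 1L))
    fmax <- max(fit); fmin <- min(fit)
    for (i in seq_len(n)) {
      delta[i] <- updateWavelength(delta[i], fit[i], fmax, fmin,
                                   cfg@alpha, cfg@epsilon)
      if (runif(1) < cfg@pHybrid) {
        xNew <- wavePropagate(X[i, ], delta[i], lb, ub)
        fNew <- objective(xNew); evals <- evals + 1L
        if (fNew < fit[i]) {
          X[i, ] <- xNew; fit[i] <- fNew; height[i] <- cfg@hMax
        } else height[i] <- height[i] - 1L
      } else {
        xNew <- woaMove(X[i, ], bestX, X, a, cfg, lb, ub)
        fNew <- objective(xNew); evals <- evals + 1L
        height[i] <- if (fNew < fit[i]) cfg@hMax else height[i] - 1L
        X[i, ] <- xNew; fit[i] <- fNew
      }
      if (fit[i] < bestF) { bestF <- fit[i]; bestX <- X[i, ] }
      if (height[i] <= 0L) {
        r <- waveRefract(X[i, ], bestX, delta[i], fit[i], lb = lb, ub = ub)
        fR <- objective(r$position); evals <- evals + 1L
        delta[i] <- delta[i] * fit[i] / ifelse(fR == 0, fit[i], fR)
        delta[i] <- max(delta[i], cfg@epsilon)
        X[i, ] <- r$position; fit[i] <- fR; height[i] <- cfg@hMax
        if (fR < bestF) { bestF <- fR; bestX <- r$position }
      }
    }
    trace[t] <- bestF
  }
  new("HybWaveResult", bestPosition = bestX, bestFitness = bestF,
      trace = trace, evaluations = as.integer(evals), config = cfg)
}

#' Standard benchmark objectives
#'
#' `sphereFunction` is the convex separable sum of squares; the
#' `rastriginFunction` is its multimodal cosine-rippled counterpart.  Both
#' have their global minimum 0 at the origin.
#'
#' @param x numeric position vector.
#' @return scalar objective value.
#' @export
sphereFunction <- function(x) sum(x^2)

#' @rdname sphereFunction
#' @export
rastriginFunction <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

#' Uniform random search at a fixed evaluation budget
#'
#' Equal-budget baseline: draws `budget` uniform points in the box and keeps
#' the best.  Used to demonstrate that the hybrid optimizer dominates blind
#' sampling.
#'
#' @param objective function to minimize.
#' @param lb,ub bounds.
#' @param budget number of evaluations.
#' @param seed RNG seed.
#' @param dim dimension (inferred from `lb` when missing).
#' @return list with `bestPosition` and `bestFitness`.
#' @export
randomSearch <- function(objective, lb, ub, budget, seed = 1L,
                         dim = length(lb)) {
  D <- as.integer(dim)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  withSeed(seed, {
    bestF <- Inf; bestX <- NULL
    for (i in seq_len(budget)) {
      x <- runif(D, lb, ub)
      f <- objective(x)
      if (f < bestF) { bestF <- f; bestX <- x }
    }
    list(bestPosition = bestX, bestFitness = bestF)
  })
}
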