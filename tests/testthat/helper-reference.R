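# Independent reference implementations used as oracles.  These are written
# from the operator definitions directly (no code shared with the package
# internals) so they can arbitrate the package's behavior.

# direct a-trous filter-bank convolution: detail/approx coefficients of one
# level with taps upsampled by 2^(j-1), periodic boundary
refSwtLevel <- function(x, h, g, j) {
  N <- length(x)
  up <- 2L^(j - 1L)
  a <- numeric(N); d <- numeric(N)
  for (n in seq_len(N)) {
    for (k in seq_along(h)) {
      src <- ((n - 1L - (k - 1L) * up) %% N) + 1L
      a[n] <- a[n] + h[k] * x[src]
      d[n] <- d[n] + g[k] * x[src]
    }
  }
  list(a = a, d = d)
}

# db2 analysis filters from the standard closed form (independent source)
refDb2 <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
}

# pure water-wave optimizer: propagation (greedy) + wavelength schedule +
# height-triggered refraction toward the best-ever solution
refWWO <- function(f, lb, ub, pop, iters, seed, alpha = 1.0026,
                   eps = 1e-12, hmax = 6L) {
  set.seed(seed)
  D <- length(lb)
  X <- t(replicate(pop, runif(D, lb, ub)))
  fit <- apply(X, 1, f)
  dl <- rep(0.5, pop)
  h <- rep(hmax, pop)
  bF <- min(fit); bX <- X[which.min(fit), ]
  for (t in seq_len(iters)) {
    fx <- max(fit); fn <- min(fit)
    for (i in seq_len(pop)) {
      dl[i] <- dl[i] * alpha^(-(fit[i] - fn + eps) / (fx - fn + eps))
      xn <- X[i, ] + runif(D, -1, 1) * dl[i] * (ub - lb)
      oo <- xn < lb | xn > ub
      xn[oo] <- lb[oo] + runif(sum(oo)) * (ub - lb)[oo]
      fnew <- f(xn)
      if (fnew < fit[i]) {
        X[i, ] <- xn; fit[i] <- fnew; h[i] <- hmax
      } else h[i] <- h[i] - 1L
      if (fit[i] < bF) { bF <- fit[i]; bX <- X[i, ] }
      if (h[i] <= 0L) {
        xr <- rnorm(D, (bX + X[i, ]) / 2, abs(bX - X[i, ]) / 2)
        xr <- pmin(pmax(xr, lb), ub)
        fr <- f(xr)
        dl[i] <- dl[i] * fit[i] / ifelse(fr == 0, fit[i], fr)
        X[i, ] <- xr; fit[i] <- fr; h[i] <- hmax
        if (fr < bF) { bF <- fr; bX <- xr }
      }
    }
  }
  bF
}

# pure whale optimizer: spiral / encircle / random-agent exploration,
# always-accept moves, a decaying linearly from 2 to 0
refWOA <- function(f, lb, ub, pop, iters, seed, b = 1) {
  set.seed(seed)
  D <- length(lb)
  X <- t(replicate(pop, runif(D, lb, ub)))
  fit <- apply(X, 1, f)
  bF <- min(fit); bX <- X[which.min(fit), ]
  for (t in seq_len(iters)) {
    a <- 2 * (1 - (t - 1) / max(1, iters - 1))
    for (i in seq_len(pop)) {
      if (runif(1) >= 0.5) {
        l <- runif(1, -1, 1)
        xn <- abs(bX - X[i, ]) * exp(b * l) * cos(2 * pi * l) + bX
      } else {
        A <- 2 * a * runif(D) - a
        C <- 2 * runif(D)
        if (all(abs(A) < 1)) {
          xn <- bX - A * abs(C * bX - X[i, ])
        } else {
          xr <- X[sample.int(pop, 1L), ]
          xn <- xr - A * abs(C * xr - X[i, ])
        }
      }
      xn <- pmin(pmax(xn, lb), ub)
      fit[i] <- f(xn)
      X[i, ] <- xn
      if (fit[i] < bF) { bF <- fit[i]; bX <- X[i, ] }
    }
  }
  bF
}
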